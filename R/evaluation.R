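#' Match rule for comparing a call to the reference EZ
#'
#' A study is *correctly localizing* when its call agrees with the
#' post-surgically confirmed EZ on both side and sublobar location.  The
#' combined temporal class is handled by the `mlt_policy`: a reference `MLT`
#' (mesial plus lateral temporal) is matched by `MT`, `LT` or `MLT` calls
#' (and symmetrically an `MLT` call matches an `MT` or `LT` reference), while
#' `MT` versus `LT` is always a mismatch.  A Negative call matches nothing.
#'
#' @param mlt_policy `"combined"` (default, the rule above) or `"strict"`
#'   (exact sublobar equality only).
#' @return An object of class `match_rule`.
#' @export
match_rule <- function(mlt_policy = c("combined", "strict")) {
  structure(list(mlt_policy = match.arg(mlt_policy)), class = "match_rule")
}

#' Does a call match the reference EZ?
#'
#' @param call,reference canonical call strings (vectorized).  The reference
#'   must not be `"Neg"` — a negative reference is undefined in this study
#'   design (every included patient has a confirmed EZ).
#' @param rule a [match_rule()].
#' @return Logical vector.
#' @export
match_call <- function(call, reference, rule = match_rule()) {
  if (any(reference == "Neg")) stop("reference EZ must not be Negative")
  n <- max(length(call), length(reference))
  call <- rep_len(call, n); reference <- rep_len(reference, n)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (call[i] == "Neg") next
    if (call_side(call[i]) != call_side(reference[i])) next
    cs <- call_sublobar(call[i]); rs <- call_sublobar(reference[i])
    ok <- cs == rs
    if (!ok && rule$mlt_policy == "combined") {
      ok <- (rs == "MLT" && cs %in% c("MT", "LT")) ||
            (cs == "MLT" && rs %in% c("MT", "LT"))
    }
    out[i] <- ok
  }
  out
}

method_call_column <- function(method) {
  cols <- c(visual = "visual_call", spm1 = "spm1_call", spm2 = "spm2_call",
            petanalysis = "petanalysis_call", mri = "mri_call")
  if (!method %in% names(cols)) stop("unknown method: ", method)
  cols[[method]]
}

#' Positive/localizing summary for one method
#'
#' Positive = call not Negative (for MRI this means lesional: unspecific and
#' normal studies are grouped with negative).  Localizing = positive and
#' matching the reference under the rule.  Non-localizing = positive but not
#' matching.
#'
#' @param tab study tibble from [load_study_table()].
#' @param method one of `"visual"`, `"spm1"`, `"spm2"`, `"petanalysis"`,
#'   `"mri"`.
#' @param rule a [match_rule()].
#' @return One-row tibble: `method`, `n`, `positive`, `negative`,
#'   `localizing`, `non_localizing` and the matching percentages.
#' @export
summarize_method <- function(tab, method, rule = match_rule()) {
  if (nrow(tab) < 1) stop("empty study table")
  calls <- tab[[method_call_column(method)]]
  pos <- calls != "Neg"
  loc <- pos & match_call(calls, tab$reference, rule)
  n <- nrow(tab)
  tibble::tibble(method = method, n = n,
                 positive = sum(pos), negative = sum(!pos),
                 localizing = sum(loc), non_localizing = sum(pos & !loc),
                 positive_pct = 100 * sum(pos) / n,
                 localizing_pct = 100 * sum(loc) / n)
}

#' Summary table across methods
#'
#' @param tab study tibble.
#' @param methods methods to include.
#' @param rule a [match_rule()].
#' @return Tibble with one row per method (the study's summary-table layout).
#' @export
summarize_study <- function(tab,
                            methods = c("visual", "spm1", "spm2",
                                        "petanalysis", "mri"),
                            rule = match_rule()) {
  dplyr::bind_rows(lapply(methods, function(m) summarize_method(tab, m, rule)))
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` between two
#' categorical raters, with `po` the observed agreement and `pe` the chance
#' agreement from the marginal products.  The confidence interval uses the
#' large-sample standard error `sqrt(po (1 - po)) / ((1 - pe) sqrt(n))`.
#'
#' @param a,b equal-length category vectors (n >= 2).
#' @param conf_level confidence level (default 0.95).
#' @return List of class `cohen_kappa`: `kappa`, `se`, `conf_int`, `po`,
#'   `pe`, `n`.
#' @export
cohen_kappa <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop("call vectors must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 paired calls")
  cats <- union(unique(a), unique(b))
  a <- factor(a, levels = cats); b <- factor(b, levels = cats)
  tab <- table(a, b)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("both raters constant and equal; kappa defined as 1")
    kappa <- 1; se <- 0
  } else {
    kappa <- (po - pe) / (1 - pe)
    se <- sqrt(po * (1 - po)) / ((1 - pe) * sqrt(n))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se,
                 conf_int = c(kappa - z * se, kappa + z * se),
                 po = po, pe = pe, n = n),
            class = "cohen_kappa")
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s), CI [%.3f, %.3f]\n", x$kappa,
              kappa_band(x$kappa), x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Verbal agreement band for a kappa value
#'
#' The study's banding: slight for kappa in (0, 0.20], fair in (0.21, 0.40],
#' moderate in (0.41, 0.60], substantial in (0.61, 0.80], excellent above
#' 0.81.  The printed cut-points leave gaps (e.g. 0.205, 0.81); values
#' falling in a gap are mapped to the lower band and flagged via the
#' `"gap"` attribute.  Non-positive kappa is `"poor"`.
#'
#' @param kappa numeric scalar in `[-1, 1]`.
#' @return Band name (character) with logical attribute `gap`.
#' @export
kappa_band <- function(kappa) {
  if (!is.numeric(kappa) || kappa < -1 || kappa > 1)
    stop("kappa must be in [-1, 1]")
  gap <- FALSE
  band <- if (kappa <= 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.21) { gap <- TRUE; "slight" }
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.41) { gap <- TRUE; "fair" }
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.61) { gap <- TRUE; "moderate" }
  else if (kappa <= 0.80) "substantial"
  else if (kappa <= 0.81) { gap <- TRUE; "substantial" }
  else "excellent"
  structure(band, gap = gap)
}

#' Exact McNemar test from discordant counts
#'
#' Paired comparison of two methods on the same subjects, using only the
#' discordant pairs: `b` subjects where the first method succeeds and the
#' second fails, `c` the reverse.  Exact binomial two-sided p value
#' `min(1, 2 P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)` — the exact
#' variant, not the chi-square approximation.
#'
#' @param b,c non-negative discordant counts.
#' @return List: `p_value`, `b`, `c`.
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0) stop("discordant counts must be non-negative")
  if (b + c == 0) {
    warning("no discordant pairs; p = 1")
    return(list(p_value = 1, b = b, c = c))
  }
  p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
  list(p_value = p, b = b, c = c)
}

#' Discordant localization counts between two methods
#'
#' @param tab study tibble.
#' @param method_a,method_b method names (see [summarize_method()]).
#' @param rule a [match_rule()].
#' @return List `b` (a localizes, b does not), `c` (the reverse).
#' @export
discordant_counts <- function(tab, method_a, method_b, rule = match_rule()) {
  ca <- tab[[method_call_column(method_a)]]
  cb <- tab[[method_call_column(method_b)]]
  la <- ca != "Neg" & match_call(ca, tab$reference, rule)
  lb <- cb != "Neg" & match_call(cb, tab$reference, rule)
  list(b = sum(la & !lb), c = sum(!la & lb))
}

#' Pearson chi-square test of association
#'
#' Plain Pearson statistic without continuity correction,
#' `df = (r - 1)(c - 1)`.
#'
#' @param tab 2-way matrix/table of non-negative counts.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero marginal")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test across groups (equal-variance).
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return List: `F`, `df`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(value ~ grp)
  s <- summary(fit)[[1]]
  if (s["Residuals", "Sum Sq"] < .Machine$double.eps * sum(value^2))
    stop("zero within-group variance everywhere; F undefined")
  list(F = s["grp", "F value"], df = c(s["grp", "Df"], s["Residuals", "Df"]),
       p_value = s["grp", "Pr(>F)"])
}

#' Full evaluation report for a study table
#'
#' Method summaries, concordance kappas (call versus reference, over the
#' side/sublobar category space with Negative as its own category) with
#' verbal bands, and pairwise exact McNemar tests on correct localization.
#'
#' @param tab study tibble from [load_study_table()].
#' @param rule a [match_rule()].
#' @param methods methods to evaluate.
#' @return List of class `ez_evaluation`: `summary` (tibble), `kappa`
#'   (tibble: method, kappa, band, ci), `mcnemar` (tibble of pairs), `n`.
#' @export
evaluate_study <- function(tab, rule = match_rule(),
                           methods = c("visual", "spm1", "spm2",
                                       "petanalysis", "mri")) {
  summ <- summarize_study(tab, methods, rule)
  kap <- dplyr::bind_rows(lapply(methods, function(m) {
    k <- cohen_kappa(tab[[method_call_column(m)]], tab$reference)
    tibble::tibble(method = m, kappa = k$kappa,
                   band = as.character(kappa_band(k$kappa)),
                   ci_lower = k$conf_int[1], ci_upper = k$conf_int[2])
  }))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  mcn <- dplyr::bind_rows(lapply(pairs, function(pr) {
    d <- discordant_counts(tab, pr[1], pr[2], rule)
    tibble::tibble(method_a = pr[1], method_b = pr[2], b = d$b, c = d$c,
                   p_value = mcnemar_exact(d$b, d$c)$p_value)
  }))
  structure(list(summary = summ, kappa = kap, mcnemar = mcn, n = nrow(tab)),
            class = "ez_evaluation")
}

#' @export
print.ez_evaluation <- function(x, ...) {
  cat(sprintf("<ez_evaluation> %d studies\n\nMethod summary:\n", x$n))
  print(x$summary)
  cat("\nConcordance with reference EZ:\n")
  print(x$kappa)
  cat("\nPairwise exact McNemar (correct localization):\n")
  print(x$mcnemar)
  invisible(x)
}
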