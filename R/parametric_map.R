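#' Normative control cohort summaries
#'
#' Stacks preprocessed control volumes into per-voxel mean and unbiased
#' variance images — the sufficient statistics for the single-subject t-map.
#' The result is independent of input order.
#'
#' @param volumes list of >= 2 [volume()]s on a common grid.
#' @param ids optional character vector of source identifiers (provenance).
#' @return An object of class `control_cohort` with fields `n`, `mean`
#'   (volume), `variance` (volume, unbiased), `ids`.
#' @export
build_cohort <- function(volumes, ids = NULL) {
  n <- length(volumes)
  if (n < 2) stop("need at least 2 control volumes")
  ref <- volumes[[1]]
  for (i in seq_along(volumes)) {
    if (!inherits(volumes[[i]], "pet_volume"))
      stop("element ", i, " is not a volume")
    if (!grids_match(ref, volumes[[i]]))
      stop("control volume ", i, " is not on the common grid")
  }
  mat <- vapply(volumes, function(v) as.numeric(v$data),
                numeric(length(ref$data)))
  mu <- rowMeans(mat)
  v <- rowSums((mat - mu)^2) / (n - 1)
  if (is.null(ids)) ids <- paste0("control", seq_len(n))
  structure(list(n = n,
                 mean = with_data(ref, array(mu, dim(ref$data))),
                 variance = with_data(ref, array(v, dim(ref$data))),
                 ids = as.character(ids)),
            class = "control_cohort")
}

#' @export
print.control_cohort <- function(x, ...) {
  cat(sprintf("<control_cohort> n = %d on a %s grid\n", x$n,
              paste(dim(x$mean$data), collapse = "x")))
  invisible(x)
}

#' Single-subject versus cohort t-map
#'
#' Two-sample pooled-variance Student statistic with a singleton first group
#' (the patient): per masked voxel,
#' `t = (mean_controls - patient) / sqrt(var_controls * (1 + 1/n))`,
#' with `df = n - 1` (the singleton contributes no variance degrees of
#' freedom).  The sign convention is *hypometabolism-positive*: t > 0 where
#' the patient is below the controls, so epileptogenic hypometabolic foci
#' appear as positive peaks.  Voxels with zero cohort variance get t = 0 (they
#' are background artifacts and must not seed clusters); their count is
#' reported in `n_zero_variance`.
#'
#' @param patient a preprocessed [volume()].
#' @param cohort a [build_cohort()] result on the same grid.
#' @param mask binary [volume()]; t is 0 off mask.
#' @return An object of class `t_stat_map`: `t` (volume), `df`, `mask`
#'   (volume), `direction = "hypometabolism"`, `n_zero_variance`.
#' @export
tmap <- function(patient, cohort, mask) {
  stopifnot(inherits(cohort, "control_cohort"))
  stop_unless_same_grid(patient, cohort$mean, "patient/cohort")
  stop_unless_same_grid(patient, mask, "patient/mask")
  sel <- mask$data != 0
  if (!any(sel)) stop("mask is empty")
  n <- cohort$n
  denom2 <- cohort$variance$data * (1 + 1 / n)
  t <- array(0, dim(patient$data))
  zero_var <- sel & denom2 <= 0
  ok <- sel & denom2 > 0
  t[ok] <- (cohort$mean$data[ok] - patient$data[ok]) / sqrt(denom2[ok])
  structure(list(t = with_data(patient, t),
                 df = n - 1L,
                 mask = mask,
                 direction = "hypometabolism",
                 n_zero_variance = sum(zero_var)),
            class = "t_stat_map")
}

#' @export
print.t_stat_map <- function(x, ...) {
  cat(sprintf("<t_stat_map> df = %d, %d in-mask voxels, max t = %.3f\n",
              x$df, sum(x$mask$data != 0), max(x$t$data)))
  invisible(x)
}

#' Significance level to one-sided t threshold
#'
#' Upper-tail Student-t quantile at level `p` (uncorrected) or `p/m`
#' (Bonferroni over the `m` in-mask voxels).  Bonferroni stands in for
#' family-wise error control: it is slightly more conservative than
#' random-field corrections but exactly testable, and reproduces the
#' qualitative behavior of corrected thresholds (very restrictive for focal
#' hypometabolism).
#'
#' @param p significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @param correction `"none"` or `"bonferroni"`.
#' @param m number of in-mask voxels (required for Bonferroni).
#' @return The t threshold.
#' @export
t_threshold <- function(p, df, correction = c("none", "bonferroni"), m = NULL) {
  correction <- match.arg(correction)
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  p_eff <- p
  if (correction == "bonferroni") {
    if (is.null(m) || m < 1) stop("m (in-mask voxel count) required for Bonferroni")
    p_eff <- p / m
  }
  if (p_eff < .Machine$double.xmin)
    stop("corrected level ", p_eff, " underflows the t quantile; use a larger p")
  thr <- stats::qt(p_eff, df, lower.tail = FALSE)
  if (!is.finite(thr))
    stop("corrected level ", p_eff, " underflows the t quantile; use a larger p")
  thr
}

#' Background mask by fractional intensity threshold
#'
#' The SPM-style analysis mask: voxels above `fraction` times the image
#' maximum (default convention 0.3).
#'
#' @param image a [volume()].
#' @param fraction threshold fraction in (0, 1).
#' @return Binary `pet_volume`.
#' @export
background_mask <- function(image, fraction = 0.3) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  mx <- max(image$data)
  if (mx <= 0) stop("cannot build a background mask from an all-zero image")
  with_data(image, (image$data > fraction * mx) * 1)
}
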