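#' @title Study-results tables (per-patient EZ calls)
#' @description
#' The validation cohort is shipped as a tab-delimited table with one row per
#' patient: the post-surgically confirmed ("reference") EZ, the call each
#' method produced (visual reading, SPM at the corrected and uncorrected
#' standard thresholds, the dynamic parametric analysis, MRI reading),
#' histopathology and the Engel outcome class.
#'
#' A *call* is either `"Neg"` (negative/non-localizing study) or a
#' `"SIDE/SUBLOBAR"` token with side `L`/`R` and sublobar class in
#' `MT, LT, MLT, F, P, O, I`.  MRI entries are free-ish lesion strings (e.g.
#' `"R/MTS"`, `"L/LT Gliosis"`, `"Non-L"`) that are mapped to calls through a
#' packaged lesion dictionary (`MTS -> MT`; named lesions keep their printed
#' side and lobe; `Non-L` means non-lesional, grouped with negative).
#' @name study_table
NULL

valid_sides <- c("L", "R")
valid_sublobar <- c("MT", "LT", "MLT", "F", "P", "O", "I")
valid_engel <- c("I", "II", "III", "IV")

#' Parse an EZ call token
#'
#' @param x character vector of tokens (`"Neg"` or `"SIDE/SUBLOBAR"`).
#' @return Canonical call strings (`"Neg"` or `"L/MT"`-style); invalid tokens
#'   raise an error naming them.
#' @export
parse_call <- function(x) {
  x <- trimws(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (x[i] %in% c("Neg", "Negative")) { out[i] <- "Neg"; next }
    parts <- strsplit(x[i], "/", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !(parts[1] %in% valid_sides) ||
        !(parts[2] %in% valid_sublobar))
      stop("malformed call token: '", x[i], "'")
    out[i] <- paste0(parts[1], "/", parts[2])
  }
  out
}

#' Side and sublobar components of canonical call strings
#' @param call canonical call string vector.
#' @return `call_side`: `"L"`, `"R"` or `"Neg"`; `call_sublobar`: sublobar
#'   class or `"Neg"`.
#' @export
call_side <- function(call) ifelse(call == "Neg", "Neg", substr(call, 1, 1))

#' @rdname call_side
#' @export
call_sublobar <- function(call) ifelse(call == "Neg", "Neg", sub("^[LR]/", "", call))

#' Default MRI lesion dictionary shipped with the package
#' @return Tibble with columns `token`, `sublobar`.
#' @export
mri_lesion_map <- function() {
  path <- system.file("extdata", "mri_lesion_map.tsv", package = "petez",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Map an MRI lesion string to a canonical call
#'
#' `"Non-L"` (and `"Neg"`) map to `"Neg"`.  Otherwise the string must read
#' `"SIDE/LESION..."`; the first token after the side is translated through
#' the lesion dictionary (e.g. `MTS -> MT`, `LT -> LT`), and the printed side
#' is kept.
#'
#' @param x character vector of MRI entries.
#' @param map lesion dictionary, default [mri_lesion_map()].
#' @return Canonical call strings.
#' @export
parse_mri_call <- function(x, map = mri_lesion_map()) {
  x <- trimws(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (x[i] %in% c("Non-L", "Neg", "Negative")) { out[i] <- "Neg"; next }
    parts <- strsplit(x[i], "/", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !(parts[1] %in% valid_sides))
      stop("malformed MRI lesion string: '", x[i], "'")
    lesion_token <- strsplit(trimws(parts[2]), "[ ]+")[[1]][1]
    j <- match(lesion_token, map$token)
    if (is.na(j))
      stop("MRI lesion token not in dictionary: '", lesion_token, "' (", x[i], ")")
    out[i] <- paste0(parts[1], "/", map$sublobar[j])
  }
  out
}

#' Load a study-results table
#'
#' Reads the per-patient table (TSV, header row) and parses every call.  The
#' returned tibble keeps the raw printed columns (so the file round-trips
#' losslessly through [write_study_table()]) and adds parsed call columns
#' `reference`, `visual`, `spm1`, `spm2`, `petanalysis`, `mri_call`.
#'
#' @param path TSV file with columns `no`, `pez`, `visual`, `spm1`, `spm2`,
#'   `petanalysis`, `mri`, `histopathology`, `engel`.
#' @param lesion_map MRI lesion dictionary, default [mri_lesion_map()].
#' @return A tibble with one row per patient.
#' @export
load_study_table <- function(path, lesion_map = mri_lesion_map()) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  needed <- c("no", "pez", "visual", "spm1", "spm2", "petanalysis", "mri",
              "histopathology", "engel")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("study table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) < 1) stop("study table is empty")
  tab <- tibble::as_tibble(raw)
  parse_col <- function(col, f) {
    vapply(seq_len(nrow(tab)), function(i) {
      tryCatch(f(tab[[col]][i]),
               error = function(e) stop("row ", i, ", column '", col, "': ",
                                        conditionMessage(e), call. = FALSE))
    }, character(1))
  }
  tab$reference <- parse_col("pez", parse_call)
  if (any(tab$reference == "Neg"))
    stop("reference EZ must not be Negative (rows ",
         paste(which(tab$reference == "Neg"), collapse = ", "), ")")
  tab$visual_call <- parse_col("visual", parse_call)
  tab$spm1_call <- parse_col("spm1", parse_call)
  tab$spm2_call <- parse_col("spm2", parse_call)
  tab$petanalysis_call <- parse_col("petanalysis", parse_call)
  tab$mri_call <- parse_col("mri", function(x) parse_mri_call(x, lesion_map))
  bad_engel <- !(tab$engel %in% valid_engel)
  if (any(bad_engel))
    stop("invalid Engel class in rows ", paste(which(bad_engel), collapse = ", "))
  tab
}

#' Serialize a study table back to TSV
#'
#' Writes the raw printed columns only, reproducing the input file of
#' [load_study_table()] byte-for-byte.
#'
#' @param tab tibble from [load_study_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(tab, path) {
  raw_cols <- c("no", "pez", "visual", "spm1", "spm2", "petanalysis", "mri",
                "histopathology", "engel")
  utils::write.table(tab[, raw_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Packaged validation-cohort fixtures
#'
#' `study_table_fixture()` returns the path of the packaged 30-patient table;
#' with `erratum = TRUE` it returns the variant in which patient 9's dynamic
#' parametric-analysis call is Negative.  The as-printed table is internally
#' inconsistent with its own summary counts by one cell; the erratum variant
#' is the corrected version (see the methods vignette).
#'
#' @param erratum logical; return the corrected variant?
#' @return File path of the TSV fixture.
#' @export
study_table_fixture <- function(erratum = FALSE) {
  fn <- if (erratum) "study_table_erratum.tsv" else "study_table.tsv"
  system.file("extdata", fn, package = "petez", mustWork = TRUE)
}
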