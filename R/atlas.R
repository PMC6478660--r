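#' Integer label atlas with a region table
#'
#' Couples an integer label volume to a lookup table describing each region:
#' its name, hemisphere (`L`, `R` or `midline`), sublobar class (`MT` mesial
#' temporal, `LT` lateral temporal, `F` frontal, `P` parietal, `O` occipital,
#' `I` insular, or `other`) and whether it is cortical.  Label 0 is background
#' and never appears in the table.
#'
#' @param labels a [volume()] of non-negative integer labels.
#' @param table a data frame with columns `id`, `name`, `side`, `sublobar`,
#'   `cortical`.
#' @return An object of class `label_atlas` with fields `labels` (volume) and
#'   `table` (tibble).
#' @export
label_atlas <- function(labels, table) {
  stopifnot(inherits(labels, "pet_volume"))
  table <- tibble::as_tibble(table)
  needed <- c("id", "name", "side", "sublobar", "cortical")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("atlas table is missing columns: ", paste(missing_cols, collapse = ", "))
  lab <- labels$data
  if (any(lab != round(lab)) || any(lab < 0))
    stop("label volume must contain non-negative integers")
  if (anyDuplicated(table$id))
    stop("duplicate label ids in atlas table: ",
         paste(unique(table$id[duplicated(table$id)]), collapse = ", "))
  if (any(table$id == 0)) stop("label 0 is reserved for background")
  present <- sort(unique(as.integer(lab[lab != 0])))
  orphan <- setdiff(present, table$id)
  if (length(orphan))
    stop("labels present in volume but absent from table: ",
         paste(orphan, collapse = ", "))
  bad_side <- setdiff(unique(table$side), c("L", "R", "midline"))
  if (length(bad_side)) stop("unknown side values: ", paste(bad_side, collapse = ", "))
  bad_sub <- setdiff(unique(table$sublobar), c("MT", "LT", "F", "P", "O", "I", "other"))
  if (length(bad_sub)) stop("unknown sublobar values: ", paste(bad_sub, collapse = ", "))
  table$cortical <- as.logical(table$cortical)
  structure(list(labels = labels, table = table), class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %d regions (%d cortical) on a %s grid\n",
              nrow(x$table), sum(x$table$cortical),
              paste(dim(x$labels$data), collapse = "x")))
  print(x$table, n = Inf)
  invisible(x)
}

#' Load a label atlas from a NIfTI volume and a TSV region table
#'
#' @param volume_path NIfTI file of integer labels.
#' @param table_path tab-delimited UTF-8 table with a header row and columns
#'   `id`, `name`, `side`, `sublobar`, `cortical`.
#' @return A [label_atlas()].
#' @export
load_atlas <- function(volume_path, table_path) {
  vol <- read_volume(volume_path)
  tab <- utils::read.delim(table_path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  label_atlas(vol, tab)
}

#' Write an atlas region table as TSV
#' @param atlas a [label_atlas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas_table <- function(atlas, path) {
  utils::write.table(atlas$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gray-matter analysis mask from an atlas
#'
#' Union of all voxels whose label is flagged cortical — the analysis mask of
#' the dedicated pipeline, restricting the statistical comparison to gray
#' matter (seizures arise in cortex, and white matter/background voxels would
#' only dilute the test).
#'
#' @param atlas a [label_atlas()].
#' @return A `pet_volume` with 1 inside cortical labels, 0 elsewhere.
#' @export
gray_matter_mask <- function(atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  cort <- atlas$table$id[atlas$table$cortical]
  m <- array(0, dim(atlas$labels$data))
  m[atlas$labels$data %in% cort] <- 1
  if (!any(m == 1)) stop("gray-matter mask is empty: no cortical labels present in volume")
  with_data(atlas$labels, m)
}

#' Look up region properties for a vector of label ids
#' @keywords internal
atlas_lookup <- function(atlas, ids) {
  atlas$table[match(ids, atlas$table$id), , drop = FALSE]
}
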