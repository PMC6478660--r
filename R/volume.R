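#' 3-D scalar volume with physical geometry
#'
#' The universal image currency of the package: a 3-D numeric grid together
#' with voxel spacing (mm per axis) and the world-space position of voxel
#' `(0, 0, 0)` (mm).  Axes follow the RAS convention — increasing x points to
#' the subject's Right, y Anterior, z Superior — so the hemisphere of a world
#' point is simply the sign of its x coordinate (positive x = Right).
#'
#' @param data numeric 3-D array; every dimension must be at least 1 and every
#'   voxel finite (images containing `NaN`/`Inf` are rejected).
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param origin numeric length-3, world coordinate (mm) of voxel `(0, 0, 0)`
#'   (0-based indexing).  Defaults to centering the grid on the world origin,
#'   which places the interhemispheric plane at x = 0.
#' @return An object of class `pet_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- volume(array(1, c(8, 8, 8)), spacing = c(2.6, 2.6, 2.4))
#' dim(v)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", if (is.array(data)) paste0(length(dim(data)), "-D") else class(data)[1])
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume contains NaN/Inf voxels")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "pet_volume")
}

#' @export
dim.pet_volume <- function(x) dim(x$data)

#' @export
as.array.pet_volume <- function(x, ...) x$data

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Replace the data grid of a volume, keeping its geometry
#'
#' @param vol a [volume()].
#' @param data a numeric array of the same dimensions.
#' @return A `pet_volume` with the same spacing/origin.
#' @export
with_data <- function(vol, data) {
  stopifnot(inherits(vol, "pet_volume"))
  if (!identical(dim(data), dim(vol$data))) stop("data dimensions do not match the volume grid")
  volume(data, vol$spacing, vol$origin)
}

grids_match <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_unless_same_grid <- function(a, b, what = "volumes") {
  if (!grids_match(a, b)) stop(what, " are not on a common grid")
  invisible(TRUE)
}

#' World coordinates of every voxel
#'
#' @param vol a [volume()].
#' @return A 3 x N matrix of world coordinates (mm), N = number of voxels, in
#'   column-major voxel order.
#' @keywords internal
voxel_world_coords <- function(vol) {
  d <- dim(vol$data)
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  rbind(vol$origin[1] + i * vol$spacing[1],
        vol$origin[2] + j * vol$spacing[2],
        vol$origin[3] + k * vol$spacing[3])
}

#' World x coordinate per voxel (hemisphere axis)
#' @keywords internal
voxel_world_x <- function(vol) {
  d <- dim(vol$data)
  x <- vol$origin[1] + (seq_len(d[1]) - 1L) * vol$spacing[1]
  array(x, d)
}

#' Read a NIfTI-1 volume
#'
#' Loads a single-file NIfTI-1 image as a [volume()].  Only 3-D images are
#' accepted; spacing is taken from the pixel dimensions and the origin from the
#' translation column of the stored transform.  Images containing `NaN` or
#' `Inf` voxels are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A `pet_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), "-D image: ", path)
  xf <- RNifti::xform(img)
  # header geometry is float32 in NIfTI-1; undo the quantization noise
  spacing <- signif(RNifti::pixdim(img)[1:3], 7)
  origin <- signif(as.numeric(xf[1:3, 4]), 7)
  dat <- array(as.numeric(img), dim = d)
  if (anyNA(dat) || any(!is.finite(dat)))
    stop("volume contains NaN/Inf voxels: ", path)
  volume(dat, spacing, origin)
}

#' Write a volume as NIfTI-1
#'
#' The grid, spacing and origin round-trip bit-identically through
#' [read_volume()] (data stored as float64; axis-aligned RAS transform with
#' sform/qform code 2).
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pet_volume"))
  a <- vol$data
  attr(a, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(a, datatype = "double")
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-channel deformation field
#'
#' Deformation fields are stored as 4-D NIfTI images whose fourth dimension
#' holds the (x, y, z) displacement in mm at each voxel.
#'
#' @param path path to the 4-D NIfTI file.
#' @return A list with `field` (4-D array, last dim = 3), `spacing`, `origin`.
#' @export
read_deformation_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4-D NIfTI with 3 channels (displacement field): ", path)
  xf <- RNifti::xform(img)
  list(field = array(as.numeric(img), dim = d),
       spacing = signif(RNifti::pixdim(img)[1:3], 7),
       origin = signif(as.numeric(xf[1:3, 4]), 7))
}

#' Write a 3-channel deformation field
#'
#' @param field 4-D array (x, y, z, 3) of mm displacements.
#' @param spacing,origin grid geometry, as for [volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deformation_field <- function(field, spacing, origin, path) {
  stopifnot(length(dim(field)) == 4L, dim(field)[4] == 3L)
  attr(field, "pixdim") <- c(spacing, 1)
  img <- RNifti::asNifti(field, datatype = "double")
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
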