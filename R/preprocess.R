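#' 12-parameter affine transform
#'
#' World-space affine with 3 translations (mm), 3 rotations (rad, about the
#' x, y, z axes), 3 scales and 3 shears.  Composition order (documented and
#' fixed): a world point `x` maps to
#' `T + Rz %*% Ry %*% Rx %*% S %*% H %*% x`,
#' where `T` is the translation, `R*` the axis rotations, `S = diag(scale)`
#' and `H` the unit upper-triangular shear matrix with entries
#' `(xy, xz, yz)`.  In resampling, the transform maps points of the *target*
#' grid's world space into the *source* image's world space (pull-back).
#'
#' @param translation,rotation,scale,shear numeric length-3 each.
#' @return An object of class `affine_transform` with the parameters and the
#'   4 x 4 homogeneous `matrix`.
#' @export
affine_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                             scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 3, length(shear) == 3)
  if (any(scale <= 0)) stop("scales must be strictly positive")
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  S <- diag(scale)
  H <- rbind(c(1, shear[1], shear[2]), c(0, 1, shear[3]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% S %*% H
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- translation
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 scale = as.numeric(scale),
                 shear = as.numeric(shear),
                 matrix = m,
                 order = "T.Rz.Ry.Rx.S.H"),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> order", x$order, "\n")
  cat("  translation (mm):", format(x$translation, digits = 4), "\n")
  cat("  rotation (rad):  ", format(x$rotation, digits = 4), "\n")
  cat("  scale:           ", format(x$scale, digits = 4), "\n")
  cat("  shear:           ", format(x$shear, digits = 4), "\n")
  invisible(x)
}

#' @rdname affine_transform
#' @export
identity_transform <- function() affine_transform()

transform_matrix <- function(transform) {
  if (inherits(transform, "affine_transform")) return(transform$matrix)
  if (is.matrix(transform) && all(dim(transform) == c(4, 4))) return(transform)
  stop("not an affine transform")
}

#' Invert an affine transform
#'
#' @param transform an [affine_transform()] or 4 x 4 matrix.
#' @return A matrix-backed `affine_transform` (parameter slots `NA`) whose
#'   matrix is the inverse.
#' @export
invert_transform <- function(transform) {
  m <- transform_matrix(transform)
  inv <- tryCatch(solve(m), error = function(e) stop("singular transform"))
  structure(list(translation = NA_real_, rotation = NA_real_,
                 scale = NA_real_, shear = NA_real_,
                 matrix = inv, order = "matrix"),
            class = "affine_transform")
}

#' Serialize / deserialize a transform as JSON
#' @param transform an [affine_transform()].
#' @param path output path.
#' @return `path` invisibly; `read_transform` returns the transform.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(order = transform$order,
                            translation = transform$translation,
                            rotation = transform$rotation,
                            scale = transform$scale,
                            shear = transform$shear),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(x$translation, x$rotation, x$scale, x$shear)
}

# Trilinear sampling of `data` at 0-based voxel coordinates (3 x N).
# Coordinates within 1e-6 of an integer are snapped so that identity
# transforms reproduce the input exactly.  Out-of-grid corners contribute 0
# (indices are clamped for safe gathering; their weights are zeroed).
sample_trilinear <- function(data, coords) {
  d <- dim(data)
  x <- coords[1, ]; y <- coords[2, ]; z <- coords[3, ]
  rx <- round(x); sn <- abs(x - rx) < 1e-6; x[sn] <- rx[sn]
  ry <- round(y); sn <- abs(y - ry) < 1e-6; y[sn] <- ry[sn]
  rz <- round(z); sn <- abs(z - rz) < 1e-6; z[sn] <- rz[sn]
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  in0x <- i0 >= 0 & i0 <= d[1] - 1; in1x <- i0 >= -1 & i0 <= d[1] - 2
  in0y <- j0 >= 0 & j0 <= d[2] - 1; in1y <- j0 >= -1 & j0 <= d[2] - 2
  in0z <- k0 >= 0 & k0 <= d[3] - 1; in1z <- k0 >= -1 & k0 <= d[3] - 2
  c0x <- pmin.int(pmax.int(i0, 0), d[1] - 1); c1x <- pmin.int(pmax.int(i0 + 1, 0), d[1] - 1)
  c0y <- pmin.int(pmax.int(j0, 0), d[2] - 1); c1y <- pmin.int(pmax.int(j0 + 1, 0), d[2] - 1)
  c0z <- pmin.int(pmax.int(k0, 0), d[3] - 1); c1z <- pmin.int(pmax.int(k0 + 1, 0), d[3] - 1)
  b0y <- d[1] * c0y; b1y <- d[1] * c1y
  b0z <- d[1] * d[2] * c0z + 1; b1z <- d[1] * d[2] * c1z + 1
  gx0 <- 1 - fx; gy0 <- 1 - fy; gz0 <- 1 - fz
  (gx0 * gy0 * gz0 * (in0x & in0y & in0z)) * data[c0x + b0y + b0z] +
  (fx  * gy0 * gz0 * (in1x & in0y & in0z)) * data[c1x + b0y + b0z] +
  (gx0 * fy  * gz0 * (in0x & in1y & in0z)) * data[c0x + b1y + b0z] +
  (fx  * fy  * gz0 * (in1x & in1y & in0z)) * data[c1x + b1y + b0z] +
  (gx0 * gy0 * fz  * (in0x & in0y & in1z)) * data[c0x + b0y + b1z] +
  (fx  * gy0 * fz  * (in1x & in0y & in1z)) * data[c1x + b0y + b1z] +
  (gx0 * fy  * fz  * (in0x & in1y & in1z)) * data[c0x + b1y + b1z] +
  (fx  * fy  * fz  * (in1x & in1y & in1z)) * data[c1x + b1y + b1z]
}

world_to_voxel <- function(vol, world) {
  (world - vol$origin) / vol$spacing
}

#' Resample an image through an affine transform
#'
#' For each voxel of the `target` grid with world coordinate `y`, the output
#' takes the trilinearly interpolated value of `image` at `transform(y)`
#' (pull-back convention).  Voxels mapping outside the field of view of
#' `image` are set to 0.  The identity transform on the image's own grid
#' returns the input bitwise.
#'
#' @param image a [volume()] to resample.
#' @param transform an [affine_transform()] (or 4 x 4 matrix) mapping target
#'   world coordinates to `image` world coordinates.
#' @param target a [volume()] whose grid (dims/spacing/origin) defines the
#'   output; its data is ignored.
#' @return A `pet_volume` on the target grid.
#' @export
resample <- function(image, transform, target = image) {
  m <- transform_matrix(transform)
  if (abs(det(m[1:3, 1:3])) < 1e-12) stop("singular transform")
  w <- voxel_world_coords(target)
  src_world <- m[1:3, 1:3] %*% w + m[1:3, 4]
  coords <- (src_world - image$origin) / image$spacing
  out <- sample_trilinear(image$data, coords)
  volume(array(out, dim(target$data)), target$spacing, target$origin)
}

#' Apply a precomputed nonlinear deformation field
#'
#' The field holds, for every voxel of the image grid, a displacement in mm;
#' the output voxel at world position `y` takes the value of `image` at
#' `y + u(y)` (pull-back interpolation).  An all-zero field is the identity.
#' Field computation itself is delegated to external registration tools; this
#' function only consumes fields.
#'
#' @param image a [volume()].
#' @param field 4-D array (same grid, last dim = 3) of mm displacements, or
#'   the list returned by [read_deformation_field()].
#' @return A `pet_volume` on the image grid.
#' @export
apply_deformation <- function(image, field) {
  if (is.list(field)) field <- field$field
  d <- dim(image$data)
  if (!identical(dim(field), c(d, 3L)) && !identical(dim(field), c(d, 3)))
    stop("deformation field shape does not match the image grid")
  w <- voxel_world_coords(image)
  u <- rbind(as.numeric(field[, , , 1]), as.numeric(field[, , , 2]),
             as.numeric(field[, , , 3]))
  coords <- (w + u - image$origin) / image$spacing
  out <- sample_trilinear(image$data, coords)
  volume(array(out, d), image$spacing, image$origin)
}

center_of_mass <- function(vol) {
  w <- voxel_world_coords(vol)
  tot <- sum(vol$data)
  if (tot <= 0) return(c(0, 0, 0))
  as.numeric(w %*% as.numeric(vol$data)) / tot
}

downsample2 <- function(vol) {
  d <- dim(vol$data)
  d2 <- pmax(d %/% 2L, 1L)
  a <- vol$data[seq_len(d2[1] * 2), seq_len(d2[2] * 2), seq_len(d2[3] * 2),
                drop = FALSE]
  a <- (a[seq(1, 2 * d2[1], 2), , , drop = FALSE] +
        a[seq(2, 2 * d2[1], 2), , , drop = FALSE]) / 2
  a <- (a[, seq(1, 2 * d2[2], 2), , drop = FALSE] +
        a[, seq(2, 2 * d2[2], 2), , drop = FALSE]) / 2
  a <- (a[, , seq(1, 2 * d2[3], 2), drop = FALSE] +
        a[, , seq(2, 2 * d2[3], 2), drop = FALSE]) / 2
  volume(a, vol$spacing * 2, vol$origin + vol$spacing / 2)
}

#' Affine spatial normalization by multi-resolution least squares
#'
#' Estimates the 12-parameter affine aligning `moving` to `template`
#' (same-modality PET, so the cost is the plain sum of squared intensity
#' differences over the template grid).  Optimization is deterministic:
#' initialization is center-of-mass alignment (no randomness), followed by
#' Nelder-Mead then quasi-Newton refinement on a coarse-to-fine pyramid of
#' `levels` resolutions.
#'
#' @param moving a [volume()] to align.
#' @param template the fixed reference [volume()].
#' @param levels number of pyramid levels (default 3; level 1 = full
#'   resolution).
#' @param max_iter per-level iteration budget for the refinement stage.
#' @param smooth_fwhm mm FWHM of the Gaussian applied to both images before
#'   cost evaluation (default 8).  Piecewise-constant PET-like images have
#'   thin-shell gradients; smoothing widens the capture range and the SSD
#'   basin.  Set 0 to register the raw intensities.
#' @return An [affine_transform()] mapping template world coordinates to
#'   moving world coordinates (ready for [resample()] onto the template
#'   grid).  The SSD at convergence is attached as attribute `cost`.
#' @export
affine_register <- function(moving, template, levels = 3, max_iter = 40,
                            smooth_fwhm = 8) {
  if (any(smooth_fwhm > 0)) {
    moving <- smooth_gaussian(moving, smooth_fwhm)
    template <- smooth_gaussian(template, smooth_fwhm)
  }
  pyr_t <- list(template); pyr_m <- list(moving)
  for (l in seq_len(levels - 1)) {
    pyr_t[[l + 1]] <- downsample2(pyr_t[[l]])
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]])
  }
  t0 <- center_of_mass(moving) - center_of_mass(template)
  par <- c(t0, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  n_eval <- 0L
  make_cost <- function(mov, tmp) {
    w <- voxel_world_coords(tmp)
    md <- dim(mov$data)
    function(p) {
      n_eval <<- n_eval + 1L
      tr <- affine_transform(p[1:3], p[4:6], pmax(p[7:9], 1e-3), p[10:12])
      m <- tr$matrix
      coords <- (m[1:3, 1:3] %*% w + m[1:3, 4] - mov$origin) / mov$spacing
      cost <- sum((sample_trilinear(mov$data, coords) - tmp$data)^2)
      if (!is.finite(cost))
        stop("non-finite registration cost at evaluation ", n_eval)
      cost
    }
  }
  scales <- c(rep(2, 3), rep(0.02, 3), rep(0.01, 3), rep(0.01, 3))
  fit <- NULL
  for (l in rev(seq_len(levels))) {
    cost <- make_cost(pyr_m[[l]], pyr_t[[l]])
    if (l == levels) {
      par <- stats::optim(par, cost, method = "Nelder-Mead",
                          control = list(maxit = 500, parscale = scales,
                                         reltol = 1e-8))$par
    }
    # iteration budget shrinks with resolution: coarse levels are cheap and
    # do the travelling, the finest level only polishes
    lvl_iter <- max(3L, ceiling(max_iter / 4^(levels - l)))
    fit <- stats::optim(par, cost, method = "BFGS",
                        control = list(maxit = lvl_iter, parscale = scales,
                                       reltol = 1e-10))
    par <- fit$par
  }
  out <- affine_transform(par[1:3], par[4:6], par[7:9], par[10:12])
  attr(out, "cost") <- fit$value
  out
}

#' Quotient-histogram parabola intensity normalization
#'
#' Estimates a single global scale factor between a patient study and a
#' reference image as the *mode* of the voxel-wise quotient distribution
#' `patient / reference` over the analysis mask, refined by a local parabola
#' fit.  Unlike a total-counts (global mean) ratio, the mode is insensitive
#' to focal intensity abnormalities — the very hypometabolic regions the
#' analysis is looking for — which would otherwise bias the factor.
#'
#' Procedure: quotients are histogrammed between their 1st and 99th
#' percentiles with `bins` equal-width bins; a parabola is least-squares
#' fitted to (bin center, count) over the modal bin +/- `half_width` bins;
#' the factor is the parabola's vertex abscissa, clamped to the fitted
#' window.  Degenerate cases (all quotients in one bin; upward-opening
#' parabola) fall back to the modal bin center and are flagged in the
#' diagnostics.
#'
#' @param patient,reference [volume()]s on a common grid.
#' @param mask binary [volume()]; quotients are computed over `mask != 0`.
#'   The reference must be strictly positive there.
#' @param bins number of histogram bins (default 100).
#' @param half_width half-width of the parabola window in bins (default 3).
#' @return A list of class `normalization_result`: `factor`, `method`
#'   (`"parabola-quotient"`), `diagnostics` (modal bin center, fitted window,
#'   bin width, flags).  The normalized image is `patient / factor`.
#' @export
intensity_normalize_parabola <- function(patient, reference, mask,
                                         bins = 100, half_width = 3) {
  stop_unless_same_grid(patient, reference, "patient/reference")
  stop_unless_same_grid(patient, mask, "patient/mask")
  sel <- mask$data != 0
  if (!any(sel)) stop("mask is empty")
  ref <- reference$data[sel]
  if (any(ref <= 0)) stop("reference must be strictly positive on masked voxels")
  q <- patient$data[sel] / ref
  lim <- stats::quantile(q, c(0.01, 0.99), names = FALSE, type = 7)
  flags <- character(0)
  if (diff(lim) < .Machine$double.eps^0.5 * max(1, abs(lim[1]))) {
    res <- list(factor = lim[1], method = "parabola-quotient",
                diagnostics = list(mode = lim[1], window = lim, bin_width = 0,
                                   bins = bins, flags = "degenerate-histogram"))
    class(res) <- "normalization_result"
    warning("degenerate quotient histogram: all quotients in one bin")
    return(res)
  }
  breaks <- seq(lim[1], lim[2], length.out = bins + 1)
  qq <- q[q >= lim[1] & q <= lim[2]]
  h <- hist(qq, breaks = breaks, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  mode_bin <- which.max(counts)
  win <- max(1, mode_bin - half_width):min(bins, mode_bin + half_width)
  x <- centers[win]; y <- counts[win]
  factor <- centers[mode_bin]
  if (length(win) >= 3) {
    fit <- stats::lm.fit(cbind(1, x, x^2), y)
    a <- fit$coefficients[3]
    if (is.finite(a) && a < 0) {
      vertex <- -fit$coefficients[2] / (2 * a)
      factor <- min(max(vertex, min(x)), max(x))
    } else {
      flags <- c(flags, "upward-parabola")
      warning("parabola opens upward; falling back to modal bin center")
    }
  }
  res <- list(factor = unname(factor), method = "parabola-quotient",
              diagnostics = list(mode = centers[mode_bin],
                                 window = range(x),
                                 bin_width = diff(centers[1:2]),
                                 bins = bins, flags = flags))
  class(res) <- "normalization_result"
  res
}

#' Proportional-scaling intensity normalization
#'
#' The SPM-style global normalization: the factor is the masked mean of the
#' image divided by a nominal grand mean, so the normalized image has masked
#' mean exactly `grand_mean`.
#'
#' @param patient a [volume()].
#' @param mask binary [volume()].
#' @param grand_mean nominal grand mean (default 50, the conventional value).
#' @return A `normalization_result` with method `"proportional-scaling"`.
#' @export
intensity_normalize_proportional <- function(patient, mask, grand_mean = 50) {
  stop_unless_same_grid(patient, mask, "patient/mask")
  sel <- mask$data != 0
  if (!any(sel)) stop("mask is empty")
  mu <- mean(patient$data[sel])
  if (abs(mu) < .Machine$double.eps) stop("zero masked mean")
  res <- list(factor = mu / grand_mean, method = "proportional-scaling",
              diagnostics = list(masked_mean = mu, grand_mean = grand_mean,
                                 flags = character(0)))
  class(res) <- "normalization_result"
  res
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> method %s, factor %.6g\n",
              x$method, x$factor))
  invisible(x)
}

#' Apply a normalization result to a volume
#' @param vol a [volume()].
#' @param norm a `normalization_result`.
#' @return The voxel-wise quotient `vol / norm$factor`.
#' @export
apply_normalization <- function(vol, norm) {
  with_data(vol, vol$data / norm$factor)
}

#' FWHM (mm) to Gaussian sigma in voxels
#'
#' @param fwhm full width at half maximum per axis, mm.
#' @param spacing voxel size per axis, mm.
#' @return `fwhm / (2 * sqrt(2 * log(2))) / spacing`, per axis.
#' @export
fwhm_to_sigma <- function(fwhm, spacing) {
  fwhm / (2 * sqrt(2 * log(2))) / spacing
}

#' Separable Gaussian smoothing
#'
#' Convolves the volume with an axis-separable Gaussian kernel specified by
#' its FWHM in mm per axis (sigma in voxels = `fwhm / (2 sqrt(2 ln 2))`
#' divided by the spacing).  The discrete kernel is truncated at 4 sigma and
#' renormalized to sum to 1, so interior intensity is conserved.  Boundary
#' handling is zero padding: intensity leaks out at the grid edge (masks that
#' are smoothed should be re-binarized at 0.5).  A zero FWHM returns the
#' input unchanged.
#'
#' @param image a [volume()].
#' @param fwhm numeric length 1 or 3, mm; must be >= 0.
#' @return The smoothed `pet_volume`.
#' @export
smooth_gaussian <- function(image, fwhm) {
  stopifnot(inherits(image, "pet_volume"))
  if (length(fwhm) == 1) fwhm <- rep(fwhm, 3)
  if (length(fwhm) != 3 || any(!is.finite(fwhm)) || any(fwhm < 0))
    stop("fwhm must be 3 non-negative numbers")
  sig <- fwhm_to_sigma(fwhm, image$spacing)
  a <- image$data
  for (axis in 1:3) {
    if (sig[axis] <= 0) next
    r <- max(1L, ceiling(4 * sig[axis]))
    k <- exp(-((-r):r)^2 / (2 * sig[axis]^2))
    k <- k / sum(k)
    a <- convolve_axis(a, k, axis)
  }
  with_data(image, a)
}

# shift-and-add separable convolution with zero padding
convolve_axis <- function(a, kernel, axis) {
  d <- dim(a)
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    w <- kernel[j]
    src_lo <- max(1L, 1L + off); src_hi <- min(n, n + off)
    if (src_lo > src_hi) next
    dst_lo <- src_lo - off; dst_hi <- src_hi - off
    if (axis == 1) {
      out[dst_lo:dst_hi, , ] <- out[dst_lo:dst_hi, , ] + w * a[src_lo:src_hi, , ]
    } else if (axis == 2) {
      out[, dst_lo:dst_hi, ] <- out[, dst_lo:dst_hi, ] + w * a[, src_lo:src_hi, ]
    } else {
      out[, , dst_lo:dst_hi] <- out[, , dst_lo:dst_hi] + w * a[, , src_lo:src_hi]
    }
  }
  out
}
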