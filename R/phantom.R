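#' Synthetic brain phantom specification
#'
#' Defines the geometry and statistics of the desk-scale phantom that stands
#' in for a normative PET database: an ellipsoidal "brain" whose interior is
#' a non-cortical core, with 10 spherical cortical blobs (left/right times
#' mesial temporal, lateral temporal, frontal, parietal, occipital) placed
#' mirror-symmetrically about the interhemispheric plane x = 0.  Control
#' subjects are the template scaled by a log-normal global factor plus
#' i.i.d. Gaussian voxel noise (truncated at 0); patients additionally carry
#' a focal spherical hypometabolic lesion (intensity multiplied by
#' `1 - lesion_contrast`) anchored at a named cortical region, and optionally
#' a random affine perturbation.
#'
#' Defaults emulate the study conditions at desk scale: 64^3 grid at
#' 2.6 x 2.6 x 2.4 mm voxels, cortical intensity 100, core 60, global-scale
#' sigma 0.15, voxel noise sigma 5 (5% of cortical intensity), 20 controls,
#' lesion of radius 4 voxels (about 270 voxels) at 20% contrast.
#'
#' @param shape grid dimensions.
#' @param spacing voxel size, mm.
#' @param brain_semiaxes ellipsoid semi-axes, mm.
#' @param blob_radius cortical blob radius, mm.
#' @param cortical_intensity,core_intensity template intensities.
#' @param sigma_g log-scale SD of the per-subject global factor.
#' @param sigma_v SD of additive voxel noise.
#' @param n_controls control cohort size.
#' @param lesion_region region name (e.g. `"L_MT"`) anchoring the lesion.
#' @param lesion_radius lesion sphere radius, voxels.
#' @param lesion_contrast contrast fraction c in `[0, 1)`.
#' @param affine_perturb optional list with `max_shift` (mm), `max_rot`
#'   (radians), `max_scale` (fractional) for random patient misalignment;
#'   `NULL` disables it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(2.6, 2.6, 2.4),
                         brain_semiaxes = c(75, 80, 70), blob_radius = 15,
                         cortical_intensity = 100, core_intensity = 60,
                         sigma_g = 0.15, sigma_v = 5, n_controls = 20,
                         lesion_region = "L_MT", lesion_radius = 4,
                         lesion_contrast = 0.2, affine_perturb = NULL) {
  if (lesion_contrast < 0 || lesion_contrast >= 1)
    stop("lesion_contrast must be in [0, 1)")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 brain_semiaxes = brain_semiaxes, blob_radius = blob_radius,
                 cortical_intensity = cortical_intensity,
                 core_intensity = core_intensity,
                 sigma_g = sigma_g, sigma_v = sigma_v,
                 n_controls = as.integer(n_controls),
                 lesion_region = lesion_region,
                 lesion_radius = lesion_radius,
                 lesion_contrast = lesion_contrast,
                 affine_perturb = affine_perturb),
            class = "phantom_spec")
}

# blob centers as fractions of the brain semi-axes, right hemisphere;
# left is the x mirror.  Scales with spec$brain_semiaxes so small desk grids
# keep the same anatomy.
phantom_blob_center_fractions <- function() {
  rbind(MT = c(20, -5, -28),
        LT = c(55, -10, -15),
        F  = c(25, 55, 10),
        P  = c(30, -45, 35),
        O  = c(22, -62, 0)) / rep(c(75, 80, 70), each = 5)
}

phantom_blob_centers <- function(spec) {
  sweep(phantom_blob_center_fractions(), 2, spec$brain_semiaxes, `*`)
}

#' Phantom region table
#' @param spec a [phantom_spec()].
#' @return Tibble in [label_atlas()] layout (10 cortical blobs + core).
#' @export
phantom_region_table <- function(spec = phantom_spec()) {
  ctr <- phantom_blob_center_fractions()
  rows <- list()
  id <- 0L
  for (side in c("L", "R")) {
    for (rg in rownames(ctr)) {
      id <- id + 1L
      rows[[id]] <- tibble::tibble(id = id, name = paste0(side, "_", rg),
                                   side = side, sublobar = rg, cortical = TRUE)
    }
  }
  dplyr::bind_rows(rows,
                   tibble::tibble(id = 11L, name = "core", side = "midline",
                                  sublobar = "other", cortical = FALSE))
}

phantom_region_center <- function(spec, name) {
  tab <- phantom_region_table(spec)
  j <- match(name, tab$name)
  if (is.na(j)) stop("unknown phantom region: ", name)
  side <- tab$side[j]
  c0 <- phantom_blob_centers(spec)[tab$sublobar[j], ]
  if (side == "L") c0[1] <- -c0[1]
  c0
}

#' Build the phantom template and its label atlas
#'
#' Deterministic for a fixed spec.  Cortical blobs take
#' `cortical_intensity`, the core `core_intensity`, background 0.  Left and
#' right blobs are mirror images about x = 0.
#'
#' @param spec a [phantom_spec()].
#' @return List `template` ([volume()]) and `atlas` ([label_atlas()]).
#' @export
make_template_and_atlas <- function(spec = phantom_spec()) {
  d <- spec$shape
  tmpl <- volume(array(0, d), spec$spacing)
  w <- voxel_world_coords(tmpl)
  brain <- colSums((w / spec$brain_semiaxes)^2) <= 1
  labels <- integer(prod(d))
  labels[brain] <- 11L
  tab <- phantom_region_table(spec)
  claimed <- rep(FALSE, prod(d))
  for (j in which(tab$cortical)) {
    ctr <- phantom_region_center(spec, tab$name[j])
    inside <- colSums((w - ctr)^2) <= spec$blob_radius^2
    if (any(inside & claimed))
      stop("phantom regions overlap: ", tab$name[j])
    claimed <- claimed | inside
    labels[inside] <- tab$id[j]
  }
  intens <- numeric(prod(d))
  intens[labels == 11L] <- spec$core_intensity
  intens[labels %in% tab$id[tab$cortical]] <- spec$cortical_intensity
  template <- volume(array(intens, d), spec$spacing)
  atlas <- label_atlas(volume(array(as.numeric(labels), d), spec$spacing), tab)
  list(template = template, atlas = atlas)
}

phantom_noise_draw <- function(spec, template) {
  g <- stats::rlnorm(1, 0, spec$sigma_g)
  noise <- if (spec$sigma_v > 0)
    array(stats::rnorm(length(template$data), 0, spec$sigma_v),
          dim(template$data))
  else array(0, dim(template$data))
  list(g = g, noise = noise)
}

#' Simulate one control subject
#'
#' `template * g + noise`, truncated at 0, with
#' `g ~ LogNormal(0, sigma_g^2)` and i.i.d. `N(0, sigma_v^2)` voxel noise.
#' Reproducible per seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @param template optional precomputed template (rebuilt if omitted).
#' @return A `pet_volume`.
#' @export
make_control <- function(spec = phantom_spec(), seed = 1, template = NULL) {
  if (is.null(template)) template <- make_template_and_atlas(spec)$template
  set.seed(seed)
  dr <- phantom_noise_draw(spec, template)
  with_data(template, pmax(template$data * dr$g + dr$noise, 0))
}

#' Simulate one lesioned patient with ground truth
#'
#' A control-like volume whose lesion sphere (radius `lesion_radius` voxels,
#' centered on the anchor region) is multiplied by `1 - lesion_contrast`
#' before global scaling and noise.  If `spec$affine_perturb` is set, a
#' random affine misalignment is applied and returned as `gt_transform` (the
#' transform that [affine_register()] against the template should recover).
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @param template,atlas optional precomputed phantom pieces.
#' @return List: `volume`, `truth` (canonical call string of the lesioned
#'   region), `lesion_voxels` (linear indices), `gt_transform` (or `NULL`),
#'   `clipped_fraction`.
#' @export
make_patient <- function(spec = phantom_spec(), seed = 1,
                         template = NULL, atlas = NULL) {
  if (is.null(template) || is.null(atlas)) {
    ta <- make_template_and_atlas(spec)
    template <- ta$template; atlas <- ta$atlas
  }
  tab <- phantom_region_table(spec)
  j <- match(spec$lesion_region, tab$name)
  if (is.na(j) || !tab$cortical[j])
    stop("lesion region must be a cortical phantom region: ", spec$lesion_region)
  d <- dim(template$data)
  ctr_mm <- phantom_region_center(spec, spec$lesion_region)
  ctr_vox <- (ctr_mm - template$origin) / template$spacing
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  jj <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  sphere <- (i - ctr_vox[1])^2 + (jj - ctr_vox[2])^2 + (k - ctr_vox[3])^2 <=
    spec$lesion_radius^2
  in_region <- atlas$labels$data == tab$id[j]
  clipped <- sum(sphere & !in_region) / sum(sphere)
  if (clipped > 0)
    warning(sprintf("lesion sphere not fully inside %s: %.1f%% clipped",
                    spec$lesion_region, 100 * clipped))
  lesioned <- template$data
  if (spec$lesion_contrast > 0)
    lesioned[sphere] <- lesioned[sphere] * (1 - spec$lesion_contrast)
  set.seed(seed)
  dr <- phantom_noise_draw(spec, template)
  vol <- with_data(template, pmax(lesioned * dr$g + dr$noise, 0))
  gt_transform <- NULL
  if (!is.null(spec$affine_perturb)) {
    pp <- spec$affine_perturb
    shift <- stats::runif(3, -pp$max_shift, pp$max_shift)
    rot <- stats::runif(3, -pp$max_rot, pp$max_rot)
    sc <- 1 + stats::runif(3, -pp$max_scale, pp$max_scale)
    gt_transform <- affine_transform(shift, rot, sc)
    vol <- resample(vol, invert_transform(gt_transform), vol)
  }
  truth <- paste0(tab$side[j], "/", tab$sublobar[j])
  list(volume = vol, truth = truth, lesion_voxels = which(sphere),
       gt_transform = gt_transform, clipped_fraction = clipped)
}
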