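# Shared desk-scale fixtures and independent oracles, built in code.

# 32^3 phantom: same anatomy as the default spec, shrunk to fit the grid.
small_spec <- function(...) {
  args <- utils::modifyList(list(shape = c(32, 32, 32),
                                 brain_semiaxes = c(34, 36, 32),
                                 blob_radius = 7, lesion_radius = 2.5),
                            list(...))
  do.call(phantom_spec, args)
}

small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_template_and_atlas(small_spec())
    cache
  }
})

default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_template_and_atlas(phantom_spec())
    cache
  }
})

# 32^3 phantom t-map with a known L/MT lesion, memoized (shared by the
# cluster and acceptance files)
lesion_tmap <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- small_spec(sigma_g = 0)
    ph <- small_phantom()
    controls <- lapply(1:20, function(i) make_control(spec, 200 + i, ph$template))
    pat <- make_patient(spec, 42, ph$template, ph$atlas)
    mask <- gray_matter_mask(ph$atlas)
    sm <- lapply(controls, smooth_gaussian, fwhm = 8)
    co <- build_cohort(sm)
    tm <- tmap(smooth_gaussian(pat$volume, 8), co, mask)
    cache <<- list(tm = tm, atlas = ph$atlas, truth = pat$truth)
    cache
  }
})

# Breadth-first-search connected components, written independently of the
# package implementation (adjacency graph + igraph).  Returns components as
# sorted integer vectors, ordered by smallest member.
bfs_components_oracle <- function(mask, connectivity = 26) {
  if (inherits(mask, "pet_volume")) mask <- mask$data
  d <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  fg <- which(mask != 0)
  visited <- logical(prod(d))
  comps <- list()
  for (start in fg) {
    if (visited[start]) next
    visited[start] <- TRUE
    queue <- start
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        ni <- co[1] + offs[r, 1]; nj <- co[2] + offs[r, 2]; nk <- co[3] + offs[r, 3]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
        lin <- ni + d[1] * (nj - 1) + d[1] * d[2] * (nk - 1)
        if (mask[lin] != 0 && !visited[lin]) {
          visited[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

canonical_components <- function(comps) {
  comps <- lapply(comps, function(x) sort(as.integer(x)))
  comps[order(vapply(comps, min, numeric(1)))]
}

# minimal in-memory study tibble with the parsed-call columns the evaluation
# functions expect
toy_study_table <- function(reference, visual = "Neg", spm1 = "Neg",
                            spm2 = "Neg", petanalysis = "Neg", mri = "Neg") {
  n <- length(reference)
  tibble::tibble(reference = reference,
                 visual_call = rep_len(visual, n),
                 spm1_call = rep_len(spm1, n),
                 spm2_call = rep_len(spm2, n),
                 petanalysis_call = rep_len(petanalysis, n),
                 mri_call = rep_len(mri, n))
}
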