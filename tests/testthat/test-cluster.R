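test_that("thresholding respects the t quantile and the mask", {
  d <- c(6, 6, 6)
  co <- build_cohort(lapply(1:20, function(i) volume(array(100 + i %% 2, d))))
  mask <- volume(array(1, d))
  tm0 <- tmap(volume(array(100.5, d)), co, mask)   # t = 0 everywhere? no: equal mean
  expect_true(all(threshold_map(tm0, threshold_spec(0.001, 1))$data == 0))

  # a single voxel with t = 10 at df = 19 survives p = 0.001 (threshold 3.58)
  tm <- tm0
  tm$t$data[3, 3, 3] <- 10
  bin <- threshold_map(tm, threshold_spec(0.001, 1))
  expect_equal(which(bin$data != 0), which(array(seq_len(prod(d)), d) ==
                                             (3 - 1) * 1 + (3 - 1) * 6 + (3 - 1) * 36 + 1))
})

test_that("supra-threshold sets nest as p loosens", {
  tm <- lesion_tmap()$tm
  ps <- c(0.0001, 0.001, 0.01, 0.05)
  sets <- lapply(ps, function(p) which(threshold_map(tm, threshold_spec(p, 1))$data != 0))
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("connectivity definitions behave at corners and edges", {
  a <- array(0, c(3, 3, 3))
  a[1, 1, 1] <- 1; a[2, 2, 2] <- 1                 # share only a corner
  expect_length(connected_components(a, 26), 1)
  expect_length(connected_components(a, 6), 2)
  b <- array(0, c(3, 3, 3))
  b[1, 1, 1] <- 1; b[2, 2, 1] <- 1                 # share an edge
  expect_length(connected_components(b, 18), 1)
  expect_length(connected_components(b, 6), 2)
  expect_equal(connected_components(array(0, c(3, 3, 3))), list())
})

test_that("components agree with the breadth-first-search oracle", {
  for (s in 1:10) {
    set.seed(s)
    a <- array(rbinom(12^3, 1, 0.35), c(12, 12, 12))
    for (conn in c(6, 18, 26)) {
      got <- canonical_components(connected_components(a, conn))
      want <- canonical_components(bfs_components_oracle(a, conn))
      expect_identical(got, want)
    }
  }
})

test_that("extent, extracortical and interhemispheric exclusions apply in order", {
  lt <- lesion_tmap()
  tm <- lt$tm; atlas <- lt$atlas
  d <- dim(tm$t$data)
  lab <- atlas$labels$data
  core_id <- atlas$table$id[!atlas$table$cortical]
  cort_ids <- atlas$table$id[atlas$table$cortical]
  wx <- abs(small_phantom()$template$origin[1] +
              (arrayInd(seq_len(prod(d)), d)[, 1] - 1) * 2.6)

  # 49 voxels at k = 50: dropped for extent before anything else
  some_cortical <- which(lab %in% cort_ids & wx > 6)
  f49 <- filter_clusters(build_clusters(list(some_cortical[1:49]), tm, atlas),
                         k = 50, atlas, tm)
  expect_length(f49$kept, 0)
  expect_equal(f49$excluded[[1]]$reason, "extent")

  core_comp <- which(lab %in% core_id & wx > 10)[1:60]   # off-midline core
  midline_comp <- which(lab %in% cort_ids & wx <= 6)     # cortical midline slab
  expect_gte(length(midline_comp), 10)
  comps <- list(some_cortical[1:9], core_comp, midline_comp,
                some_cortical[1:200])
  clusters <- build_clusters(comps, tm, atlas)
  f <- filter_clusters(clusters, k = 10, atlas, tm, midline_margin = 6)
  reasons <- vapply(f$excluded, function(e) e$reason, character(1))
  expect_length(f$kept, 1)
  expect_equal(f$kept[[1]]$size, 200)
  expect_equal(reasons, c("extent", "extracortical", "interhemispheric"))
})

test_that("ranking is size-dominant with peak-t tie-break", {
  mk <- function(size, peak, pv = c(0, 0, 0)) {
    structure(list(voxels = seq_len(size), size = size, peak_t = peak,
                   peak_voxel = pv, centroid_mm = c(0, 0, 0),
                   label_counts = table(1)), class = "ez_cluster")
  }
  seg <- rank_clusters(list(mk(120, 6.0), mk(300, 4.1)))
  expect_equal(seg$clusters[[1]]$size, 300)        # biggest first
  seg2 <- rank_clusters(list(mk(100, 4.2, c(1, 0, 0)), mk(100, 5.0, c(2, 0, 0))))
  expect_equal(seg2$clusters[[1]]$peak_t, 5.0)     # peak t breaks the tie
  seg3 <- rank_clusters(list(mk(80, 3.0)))
  expect_length(seg3$clusters, 1)
})

test_that("EZ calls carry side and sublobar class, with the MLT dual rule", {
  lt <- lesion_tmap()
  tm <- lt$tm; atlas <- lt$atlas
  lab <- atlas$labels$data
  id_of <- function(nm) atlas$table$id[atlas$table$name == nm]

  inside <- which(lab == id_of("L_MT"))[1:40]
  seg <- rank_clusters(build_clusters(list(inside), tm, atlas))
  expect_equal(ez_call(seg, atlas), "L/MT")

  expect_equal(ez_call(rank_clusters(list()), atlas), "Neg")

  # a cluster spanning mesial and lateral temporal cortex 50/50 is combined
  both <- c(which(lab == id_of("L_MT"))[1:30], which(lab == id_of("L_LT"))[1:30])
  seg2 <- rank_clusters(build_clusters(list(both), tm, atlas))
  expect_equal(ez_call(seg2, atlas), "L/MLT")

  # only non-cortical labels should have been excluded before the call
  core <- which(lab == atlas$table$id[!atlas$table$cortical])[1:30]
  seg3 <- rank_clusters(build_clusters(list(core), tm, atlas))
  expect_error(ez_call(seg3, atlas), "excluded upstream")
})

test_that("the sweep re-thresholds one t-map consistently with single runs", {
  lt <- lesion_tmap()
  sw <- threshold_sweep(lt$tm, lt$atlas, k_grid = c(10, 20, 30, 40))
  expect_equal(nrow(sw), 24)
  expect_s3_class(sw, "ez_sweep")
  # identical to independent single-spec segmentations
  for (r in c(1, 7, 14, 24)) {
    seg <- segment_tmap(lt$tm, threshold_spec(sw$p[r], sw$k[r]), lt$atlas)
    expect_identical(sw$ez[r], ez_call(seg, lt$atlas))
    expect_identical(sw$n_clusters[r], length(seg$clusters))
  }
  # cluster count is non-increasing in k at fixed p
  for (p in unique(sw$p)) {
    cnt <- sw$n_clusters[sw$p == p][order(sw$k[sw$p == p])]
    expect_true(all(diff(cnt) <= 0))
  }
  # the phantom lesion is found across the p grid at the smallest extent
  expect_true(all(sw$ez[sw$k == 10] == lt$truth))
})

test_that("sweep and t-map plots build ggplot objects", {
  lt <- lesion_tmap()
  sw <- threshold_sweep(lt$tm, lt$atlas, p_grid = c(0.05, 0.001),
                        k_grid = c(10, 20))
  p1 <- ggplot2::autoplot(sw)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_tmap_slice(lt$tm)
  expect_s3_class(p2, "ggplot")
})

test_that("kept clusters nest across p into supra-threshold components", {
  lt <- lesion_tmap()
  tm <- lt$tm
  for (pair in list(c(0.001, 0.01), c(0.0005, 0.05))) {
    seg_strict <- segment_tmap(tm, threshold_spec(pair[1], 20), lt$atlas)
    comps_loose <- connected_components(threshold_map(tm, threshold_spec(pair[2], 1)))
    for (cl in seg_strict$clusters) {
      holders <- sum(vapply(comps_loose, function(cc) any(cl$voxels %in% cc),
                            logical(1)))
      expect_equal(holders, 1)
      inside <- any(vapply(comps_loose, function(cc) all(cl$voxels %in% cc),
                           logical(1)))
      expect_true(inside)
    }
  }
})
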