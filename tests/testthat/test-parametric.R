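test_that("cohort statistics are exact and order-independent", {
  d <- c(5, 5, 5)
  v3 <- volume(array(3, d)); v5 <- volume(array(5, d))
  co <- build_cohort(list(v3, v5))
  expect_equal(co$mean$data, array(4, d))
  expect_equal(co$variance$data, array(2, d))   # unbiased: (1 + 1)/(2 - 1)

  set.seed(8)
  vols <- lapply(1:6, function(i) volume(array(rnorm(prod(d), 100, 5), d)))
  a <- build_cohort(vols)
  b <- build_cohort(rev(vols))
  expect_equal(a$mean$data, b$mean$data)
  expect_equal(a$variance$data, b$variance$data)

  expect_error(build_cohort(list(v3)), "at least 2")
  expect_error(build_cohort(list(v3, volume(array(1, c(4, 4, 4))))),
               "common grid")
})

test_that("phantom cohort variance tracks the generative noise level", {
  spec <- small_spec(sigma_g = 0, sigma_v = 5)
  tmpl <- small_phantom()$template
  controls <- lapply(1:20, function(i) make_control(spec, i, tmpl))
  co <- build_cohort(controls)
  interior <- tmpl$data > 0
  expect_lt(abs(mean(co$variance$data[interior]) - 25) / 25, 0.2)
})

test_that("the t statistic follows the singleton-group pooled formula", {
  d <- c(4, 4, 4)
  # 20 controls engineered to exact mean 100 and unbiased variance 25
  z <- as.numeric(scale(1:20))
  controls <- lapply(z, function(zi) volume(array(100 + 5 * zi, d)))
  co <- build_cohort(controls)
  expect_equal(co$mean$data[1], 100)
  expect_equal(co$variance$data[1], 25)
  mask <- volume(array(1, d))
  tm <- tmap(volume(array(90, d)), co, mask)
  expect_equal(tm$df, 19)
  expect_equal(tm$t$data[2, 2, 2], 10 / sqrt(25 * 1.05), tolerance = 1e-10)
  expect_equal(tm$t$data[2, 2, 2], 1.9518, tolerance = 1e-4)
  # patient equal to the cohort mean -> t identically 0
  tm0 <- tmap(volume(array(100, d)), co, mask)
  expect_true(all(tm0$t$data == 0))
})

test_that("the t-map equals a brute-force per-voxel two-group t-test", {
  d <- c(6, 6, 6)
  worst <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 8
    controls <- lapply(1:n, function(i) volume(array(rnorm(prod(d), 100, 10), d)))
    patient <- volume(array(rnorm(prod(d), 95, 10), d))
    co <- build_cohort(controls)
    tm <- tmap(patient, co, volume(array(1, d)))
    cmat <- sapply(controls, function(v) as.numeric(v$data))
    for (vx in seq_len(prod(d))) {
      tt <- t.test(cmat[vx, ], patient$data[vx], var.equal = TRUE)
      worst <- max(worst, abs(tm$t$data[vx] - unname(tt$statistic)))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("the t-map is location and scale invariant", {
  d <- c(6, 6, 6)
  set.seed(123)
  controls <- lapply(1:10, function(i) volume(array(rnorm(prod(d), 100, 8), d)))
  patient <- volume(array(rnorm(prod(d), 96, 8), d))
  mask <- volume(array(1, d))
  base <- tmap(patient, build_cohort(controls), mask)$t$data
  shifted <- tmap(with_data(patient, patient$data + 37),
                  build_cohort(lapply(controls, function(v)
                    with_data(v, v$data + 37))), mask)$t$data
  expect_lt(max(abs(base - shifted)), 1e-8)
  scaled <- tmap(with_data(patient, patient$data * 4.2),
                 build_cohort(lapply(controls, function(v)
                   with_data(v, v$data * 4.2))), mask)$t$data
  expect_lt(max(abs(base - scaled)), 1e-8)
})

test_that("zero-variance voxels yield t = 0 and are counted", {
  d <- c(4, 4, 4)
  controls <- lapply(1:5, function(i) {
    a <- array(100, d)
    a[2:4, , ] <- 100 + i          # variance only outside the first slab
    volume(a)
  })
  patient <- volume(array(90, d))
  tm <- tmap(patient, build_cohort(controls), volume(array(1, d)))
  expect_equal(tm$n_zero_variance, 16)
  expect_true(all(tm$t$data[1, , ] == 0))
  expect_true(all(tm$t$data[2:4, , ] > 0))
})

test_that("significance levels convert to one-sided t thresholds", {
  expect_equal(t_threshold(0.001, 29), 3.396, tolerance = 1e-3)
  expect_equal(t_threshold(0.05, 1e6), 1.6449, tolerance = 5e-4)
  expect_equal(t_threshold(0.05, 19, "bonferroni", m = 1), t_threshold(0.05, 19))
  expect_gt(t_threshold(0.05, 19, "bonferroni", m = 1000), t_threshold(0.05, 19))
  expect_error(t_threshold(1e-10, 19, "bonferroni", m = 1e300), "larger p")
  expect_error(t_threshold(0, 19), "in \\(0, 1\\)")
  expect_error(t_threshold(0.05, 19, "bonferroni"), "required")
})

test_that("background masks threshold at a fraction of the maximum", {
  a <- array(0, c(4, 4, 4)); a[1, 1, 1] <- 200; a[2, 1, 1] <- 61; a[3, 1, 1] <- 59
  v <- volume(a)
  m <- background_mask(v, 0.3)             # threshold at 60
  expect_equal(m$data[1, 1, 1], 1)
  expect_equal(m$data[2, 1, 1], 1)
  expect_equal(m$data[3, 1, 1], 0)
  expect_true(all(background_mask(volume(array(5, c(3, 3, 3))), 0.3)$data == 1))
  expect_error(background_mask(volume(array(0, c(3, 3, 3)))), "all-zero")
  # mask size non-increasing in the fraction on a phantom control
  ctrl <- make_control(small_spec(), 2, small_phantom()$template)
  sizes <- sapply(seq(0.1, 0.9, 0.1), function(f)
    sum(background_mask(ctrl, f)$data))
  expect_true(all(diff(sizes) <= 0))
})
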