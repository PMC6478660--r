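const_vol <- function(value, d = c(10, 10, 10)) volume(array(value, d))

test_that("proportional scaling pins the masked mean to the grand mean", {
  mask <- const_vol(1)
  expect_equal(intensity_normalize_proportional(const_vol(50), mask, 50)$factor, 1)
  expect_equal(intensity_normalize_proportional(const_vol(100), mask, 50)$factor, 2)
  set.seed(3)
  img <- volume(array(runif(1000, 10, 90), c(10, 10, 10)))
  n <- intensity_normalize_proportional(img, mask, 50)
  expect_equal(mean(apply_normalization(img, n)$data), 50, tolerance = 1e-10)
  expect_error(intensity_normalize_proportional(const_vol(0), mask), "zero masked mean")
})

test_that("an exact global scale is recovered through the degenerate path", {
  ref <- volume(array(runif(512, 50, 150), c(8, 8, 8)))
  pat <- with_data(ref, ref$data * 2)
  mask <- with_data(ref, array(1, dim(ref$data)))
  expect_warning(n <- intensity_normalize_parabola(pat, ref, mask), "degenerate")
  expect_equal(n$factor, 2)
  expect_equal(apply_normalization(pat, n)$data, ref$data)
})

test_that("the parabola fit locates the mode of a unimodal quotient sample", {
  set.seed(7)
  d <- c(22, 22, 22)                       # > 10^4 masked voxels
  ref <- volume(array(100, d))
  q <- rnorm(prod(d), 1.2, 0.05)
  pat <- volume(array(100 * q, d))
  mask <- volume(array(1, d))
  n <- intensity_normalize_parabola(pat, ref, mask, bins = 100, half_width = 3)
  expect_lt(abs(n$factor - 1.2), 0.01)
  expect_equal(n$method, "parabola-quotient")
})

test_that("hot-spot contamination biases the mean ratio but not the mode", {
  set.seed(11)
  d <- c(22, 22, 22)
  nv <- prod(d)
  q <- rnorm(nv, 1.0, 0.03)
  hot <- sample.int(nv, round(0.1 * nv))
  q[hot] <- 3.0
  ref <- volume(array(100, d))
  pat <- volume(array(100 * q, d))
  mask <- volume(array(1, d))
  n <- intensity_normalize_parabola(pat, ref, mask)
  expect_lt(abs(n$factor - 1.0), 0.02)
  mean_ratio <- mean(pat$data) / mean(ref$data)
  expect_gt(mean_ratio, 1.15)              # the bias the mode estimate avoids
})

test_that("the parabola factor is homogeneous of degree 1 in the patient", {
  set.seed(5)
  d <- c(16, 16, 16)
  ref <- volume(array(runif(prod(d), 80, 120), d))
  pat <- with_data(ref, ref$data * rnorm(prod(d), 1.1, 0.04))
  mask <- with_data(ref, array(1, d))
  base <- intensity_normalize_parabola(pat, ref, mask)
  for (c0 in c(0.5, 2, 3)) {
    scaled <- intensity_normalize_parabola(with_data(pat, pat$data * c0), ref, mask)
    expect_lt(abs(scaled$factor - c0 * base$factor),
              c0 * base$diagnostics$bin_width + 1e-12)
  }
})

test_that("FWHM converts to sigma in voxels by the closed form", {
  expect_equal(fwhm_to_sigma(8, 2), 1.6986, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(c(8, 8, 8), c(2.6, 2.6, 2.4)),
               8 / (2 * sqrt(2 * log(2))) / c(2.6, 2.6, 2.4))
})

test_that("smoothing is identity at zero FWHM and conserves interior mass", {
  set.seed(1)
  v <- volume(array(runif(17^3), c(17, 17, 17)), spacing = c(2.6, 2.6, 2.4))
  expect_identical(smooth_gaussian(v, 0)$data, v$data)
  expect_error(smooth_gaussian(v, -1), "non-negative")
  spike <- volume(array(0, c(17, 17, 17)), spacing = c(2.6, 2.6, 2.4))
  spike$data[9, 9, 9] <- 1
  sm <- smooth_gaussian(spike, 8)          # kernel support well inside grid
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
})

test_that("smoothing is linear and commutes with global scaling", {
  set.seed(2)
  v <- volume(array(runif(12^3), c(12, 12, 12)), spacing = c(2, 2, 2))
  a <- smooth_gaussian(with_data(v, 3.7 * v$data), 6)$data
  b <- 3.7 * smooth_gaussian(v, 6)$data
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("separable smoothing matches a dense 3-D convolution oracle", {
  set.seed(9)
  d <- c(9, 9, 9)
  v <- volume(array(runif(prod(d)), d), spacing = c(2, 2, 2))
  fwhm <- c(5, 6, 4)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / v$spacing
  r <- pmax(1, ceiling(4 * sig))
  k1 <- lapply(1:3, function(a) {
    k <- exp(-((-r[a]):r[a])^2 / (2 * sig[a]^2)); k / sum(k)
  })
  # brute-force triple loop with zero padding
  oracle <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0
    for (a in -r[1]:r[1]) for (b in -r[2]:r[2]) for (cc in -r[3]:r[3]) {
      ii <- i + a; jj <- j + b; kk <- k + cc
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      acc <- acc + k1[[1]][a + r[1] + 1] * k1[[2]][b + r[2] + 1] *
        k1[[3]][cc + r[3] + 1] * v$data[ii, jj, kk]
    }
    oracle[i, j, k] <- acc
  }
  expect_equal(smooth_gaussian(v, fwhm)$data, oracle, tolerance = 1e-12)
})
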