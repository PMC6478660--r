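test_that("the match rule honors side, sublobar class and the combined policy", {
  expect_true(match_call("L/MT", "L/MLT"))        # combined reference
  expect_true(match_call("L/LT", "L/MLT"))
  expect_true(match_call("L/MLT", "L/MT"))        # symmetric
  expect_false(match_call("R/LT", "R/MT"))        # MT vs LT is a mismatch
  expect_false(match_call("L/MT", "R/MT"))        # wrong side
  expect_false(match_call("Neg", "L/MT"))         # negative matches nothing
  expect_true(match_call("R/P", "R/P"))           # reflexive
  expect_error(match_call("L/MT", "Neg"), "Negative")
  strict <- match_rule("strict")
  expect_false(match_call("L/MT", "L/MLT", strict))
  expect_true(match_call("L/MLT", "L/MLT", strict))
})

test_that("method summaries reproduce the printed cohort margins", {
  tab <- load_study_table(study_table_fixture())
  s <- summarize_study(tab)
  get <- function(m, col) s[[col]][s$method == m]
  expect_equal(get("visual", "positive"), 28)
  expect_equal(get("visual", "localizing"), 21)
  expect_equal(get("spm1", "positive"), 1)
  expect_equal(get("spm1", "localizing"), 0)
  expect_equal(get("spm2", "positive"), 18)
  expect_equal(get("spm2", "localizing"), 11)
  expect_equal(get("petanalysis", "positive"), 30)
  expect_equal(get("mri", "positive"), 16)
  expect_equal(get("mri", "localizing"), 16)
  expect_equal(get("mri", "non_localizing"), 0)
  expect_equal(get("visual", "localizing_pct"), 70, tolerance = 1e-10)

  allneg <- toy_study_table(reference = rep("L/MT", 4))
  s0 <- summarize_method(allneg, "visual")
  expect_equal(s0$positive, 0)
  expect_equal(s0$localizing, 0)
  expect_error(summarize_method(tab, "pet"), "unknown method")
})

test_that("kappa follows the agreement-table arithmetic with its CI", {
  x <- c(rep("A", 6), rep("B", 4))
  expect_equal(cohen_kappa(x, x)$kappa, 1)
  # 2x2 table (10, 5 / 5, 10): po = 2/3, pe = 1/2, kappa = 1/3
  a <- c(rep("X", 15), rep("Y", 15))
  b <- c(rep("X", 10), rep("Y", 5), rep("X", 5), rep("Y", 10))
  k <- cohen_kappa(a, b)
  expect_equal(k$po, 2 / 3)
  expect_equal(k$pe, 1 / 2)
  expect_equal(k$kappa, 1 / 3)
  expect_equal(k$conf_int[2] - k$conf_int[1],
               2 * 1.959964 * sqrt((2 / 3) * (1 / 3)) / ((1 / 2) * sqrt(30)),
               tolerance = 1e-6)
  # constant rater vs any other rater: po = pe exactly, kappa 0
  const <- rep("X", 20)
  other <- rep(c("X", "Y"), 10)
  expect_equal(cohen_kappa(const, other)$kappa, 0, tolerance = 1e-12)
  expect_warning(k1 <- cohen_kappa(const, const), "constant")
  expect_equal(k1$kappa, 1)
})

test_that("kappa values band into the verbal agreement categories", {
  expect_equal(as.character(kappa_band(0.643)), "substantial")
  expect_equal(as.character(kappa_band(0.622)), "substantial")
  expect_equal(as.character(kappa_band(0.242)), "fair")
  expect_equal(as.character(kappa_band(0.520)), "moderate")
  expect_equal(as.character(kappa_band(0.9)), "excellent")
  expect_equal(as.character(kappa_band(0.1)), "slight")
  expect_equal(as.character(kappa_band(-0.2)), "poor")
  # boundary gap values map to the lower band and are flagged
  b81 <- kappa_band(0.81)
  expect_equal(as.character(b81), "substantial")
  expect_true(attr(b81, "gap"))
  expect_equal(as.character(kappa_band(0.82)), "excellent")
  b205 <- kappa_band(0.205)
  expect_equal(as.character(b205), "slight")
  expect_true(attr(b205, "gap"))
  expect_error(kappa_band(1.2), "\\[-1, 1\\]")
})

test_that("exact McNemar agrees with full binomial enumeration", {
  expect_equal(mcnemar_exact(7, 7)$p_value, 1)
  expect_warning(p0 <- mcnemar_exact(0, 0)$p_value, "no discordant")
  expect_equal(p0, 1)
  for (n in 1:25) {
    for (b in 0:n) {
      cc <- n - b
      # direct enumeration of Binomial(n, 1/2)
      p_enum <- min(1, 2 * sum(choose(n, 0:min(b, cc))) / 2^n)
      expect_equal(mcnemar_exact(b, cc)$p_value, p_enum, tolerance = 1e-12)
    }
  }
})

test_that("discordant pairs from the cohort fixture give the printed p values", {
  tab <- load_study_table(study_table_fixture())
  d1 <- discordant_counts(tab, "visual", "spm2")
  expect_equal(c(d1$b, d1$c), c(14, 4))
  expect_equal(round(mcnemar_exact(d1$b, d1$c)$p_value, 4), 0.0309)
  tab_err <- load_study_table(study_table_fixture(erratum = TRUE))
  d2 <- discordant_counts(tab_err, "petanalysis", "spm2")
  expect_equal(c(d2$b, d2$c), c(10, 1))
  expect_equal(round(mcnemar_exact(d2$b, d2$c)$p_value, 4), 0.0117)
})

test_that("chi-square and ANOVA wrap the classical tests", {
  even <- matrix(10, 2, 2)
  cs <- chi_square(even)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p_value, 1)
  cs2 <- chi_square(matrix(c(20, 5, 5, 20), 2))
  expect_equal(cs2$statistic, 18)
  expect_equal(cs2$df, 1)
  perm <- chi_square(matrix(c(5, 20, 20, 5), 2))
  expect_equal(perm$statistic, cs2$statistic)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "marginal")

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  av <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(av$F, 13.5)
  shifted <- one_way_anova(list(c(1, 2, 3) + 100, c(4, 5, 6) + 100))
  expect_equal(shifted$F, av$F)
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "zero within-group")
  expect_error(one_way_anova(list(1:3)), "2 groups")
})

test_that("the full evaluation report assembles summaries, kappas and tests", {
  tab <- load_study_table(study_table_fixture())
  ev <- evaluate_study(tab)
  expect_s3_class(ev, "ez_evaluation")
  expect_equal(nrow(ev$summary), 5)
  expect_equal(nrow(ev$mcnemar), 10)
  expect_true(all(ev$kappa$band %in%
                    c("poor", "slight", "fair", "moderate", "substantial",
                      "excellent")))
  vr <- ev$mcnemar[ev$mcnemar$method_a == "visual" & ev$mcnemar$method_b == "spm2", ]
  expect_equal(round(vr$p_value, 4), 0.0309)
})
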