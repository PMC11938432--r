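test_that("standard errors are recovered from printed interval spans", {
  expect_equal(se_from_interval(0.19, 1.61), 0.36225, tolerance = 1e-4)
  expect_identical(se_from_interval(0, 0), 0)
  expect_equal(se_from_interval(-1, 1), 0.51021, tolerance = 1e-4)
  expect_error(se_from_interval(1, 0), "upper bound below lower")
  expect_error(se_from_interval(0, 1, level = 1), "between 0 and 1")
})

test_that("se_from_interval is linear in width and shift-invariant", {
  withr::local_seed(11)
  for (i in 1:25) {
    lo <- rnorm(1); w <- rexp(1); shift <- rnorm(1); k <- rexp(1)
    base <- se_from_interval(lo, lo + w)
    expect_equal(se_from_interval(lo + shift, lo + w + shift), base)
    expect_equal(se_from_interval(lo, lo + k * w), k * base)
  }
})

test_that("change-SD imputation follows the correlated-difference formula", {
  expect_identical(impute_change_sd(1, 1, 1), 0)
  expect_equal(impute_change_sd(1, 1, 0.5), 1)
  expect_equal(impute_change_sd(2, 3, 0.5), sqrt(7))
  expect_equal(impute_change_sd(2, 3, 0.5), 2.64575, tolerance = 1e-5)
  expect_error(impute_change_sd(1, 1, 1.2), "<= 1")
  expect_error(impute_change_sd(-1, 1, 0), "> 0")
})

test_that("correlation pooling averages per-triple correlations", {
  est <- estimate_correlation(data.frame(sd_baseline = 1, sd_followup = 1,
                                         sd_change = 1))
  expect_equal(est$r, 0.5)
  expect_identical(est$n_pairs, 1L)

  expect_equal(estimate_correlation(
    data.frame(sd_baseline = 1, sd_followup = 1, sd_change = 0))$r, 1)

  two <- estimate_correlation(data.frame(
    sd_baseline = c(1, 2), sd_followup = c(1, 3),
    sd_change = c(1, sqrt(7))))
  expect_equal(two$r, 0.5)
  expect_identical(two$n_pairs, 2L)

  expect_error(estimate_correlation(data.frame()), "at least one")
})

test_that("imputation and correlation estimation are mutual inverses", {
  withr::local_seed(7)
  for (i in 1:50) {
    sd_b <- rexp(1) + 0.1
    sd_f <- rexp(1) + 0.1
    r <- runif(1, -0.99, 0.99)
    sd_c <- impute_change_sd(sd_b, sd_f, r)
    back <- estimate_correlation(data.frame(
      sd_baseline = sd_b, sd_followup = sd_f, sd_change = sd_c))
    expect_equal(back$r, r, tolerance = 1e-12)
  }
})

test_that("trial-level direct estimates pool arm variances", {
  tr <- trial_record("t", 52, list(
    list(treatment = "lagh", outcomes = list(
      igf1_sds = continuous_arm(100, change_mean = 1, change_sd = 1))),
    list(treatment = "daily_somatropin", outcomes = list(
      igf1_sds = continuous_arm(100, change_mean = 0, change_sd = 1)))))
  de <- trial_direct_estimate(tr, "igf1_sds")
  expect_identical(de$treatment_a, "lagh")
  expect_identical(de$treatment_b, "daily_somatropin")
  expect_equal(de$md, 1)
  expect_equal(de$se, sqrt(2 / 100))
  expect_equal(de$se, 0.14142, tolerance = 1e-5)

  same <- trial_record("t", 52, list(
    list(treatment = "lagh", outcomes = list(
      igf1_sds = continuous_arm(50, change_mean = 0.4, change_sd = 2))),
    list(treatment = "daily_somatropin", outcomes = list(
      igf1_sds = continuous_arm(50, change_mean = 0.4, change_sd = 2)))))
  expect_equal(trial_direct_estimate(same, "igf1_sds")$md, 0)
})

test_that("change-SD imputation is a fallback and reported SDs win", {
  needs_impute <- trial_record("t", 52, list(
    list(treatment = "lagh", outcomes = list(
      height_sds = continuous_arm(100, baseline_mean = 0, baseline_sd = 1,
                                  followup_mean = 1, followup_sd = 1))),
    list(treatment = "daily_somatropin", outcomes = list(
      height_sds = continuous_arm(100, change_mean = 0, change_sd = 1)))))
  de <- trial_direct_estimate(needs_impute, "height_sds", r = 0.5)
  # imputed sd_change = 1 in the first arm, so se = sqrt(1/100 + 1/100)
  expect_equal(de$se, sqrt(2 / 100))
  expect_identical(attr(de, "imputed"), c(TRUE, FALSE))
  expect_error(trial_direct_estimate(needs_impute, "height_sds"),
               "no correlation")

  both <- trial_record("t", 52, list(
    list(treatment = "lagh", outcomes = list(
      height_sds = continuous_arm(100, baseline_mean = 0, baseline_sd = 5,
                                  followup_mean = 1, followup_sd = 5,
                                  change_mean = 1, change_sd = 1))),
    list(treatment = "daily_somatropin", outcomes = list(
      height_sds = continuous_arm(100, change_mean = 0, change_sd = 1)))))
  # reported change_sd (1) wins over the imputable value (5)
  expect_equal(trial_direct_estimate(both, "height_sds", r = 0.5)$se,
               sqrt(2 / 100))
})

test_that("a missing outcome raises a feasibility error, never a silent drop", {
  tr <- trial_record("t", 52, list(
    list(treatment = "lagh", outcomes = list(
      igf1_sds = continuous_arm(10, change_mean = 1, change_sd = 1))),
    list(treatment = "daily_somatropin", outcomes = list(
      sae = binary_arm(10, 0)))))
  expect_error(trial_direct_estimate(tr, "igf1_sds"),
               class = "lagnma_feasibility_error")
})

test_that("the preprocessing ledger distinguishes reported from imputed SDs", {
  recs <- read_trials(lagnma_extdata("base_case.csv"))
  led <- preprocessing_ledger(recs, r = 0.6)
  expect_true(all(c("reported", "imputed") %in% led$sd_status))
  imputed <- led[led$sd_status == "imputed", ]
  # only the thornton bone-age rows lack a reported change SD in the fixture
  expect_true(all(imputed$outcome == "ba_ca_ratio"))
  led_no_r <- preprocessing_ledger(recs)
  expect_true("unavailable" %in% led_no_r$sd_status)
})

test_that("complete triples are harvested for correlation estimation", {
  recs <- read_trials(lagnma_extdata("base_case.csv"))
  tri <- complete_sd_triples(recs)
  expect_true(nrow(tri) >= 10)
  est <- estimate_correlation(tri)
  expect_true(abs(est$r) <= 1)
  expect_identical(est$n_pairs, nrow(tri))
})
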