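test_that("model specs validate their invariants", {
  expect_error(nma_model_spec("continuous", chains = 1), "2 chains")
  expect_error(nma_model_spec("continuous", iterations = 100, burn_in = 100),
               "burn_in")
  expect_error(nma_model_spec("continuous", prior_sd_d = 0), "prior SDs")
  s <- nma_model_spec("binary", seed = 9)
  expect_identical(s$effects, "fixed")
})

test_that("identical spec and seed give bit-identical draws", {
  net <- custom_net(star_trials(c(lagh = 0.5), 0.1))
  a <- fit_continuous(net, quick_spec(seed = 123, iterations = 1500,
                                      burn_in = 500))
  b <- fit_continuous(net, quick_spec(seed = 123, iterations = 1500,
                                      burn_in = 500))
  expect_identical(a$d, b$d)
  expect_identical(a$mu, b$mu)
  c_ <- fit_continuous(net, quick_spec(seed = 124, iterations = 1500,
                                       burn_in = 500))
  expect_false(identical(a$d, c_$d))
})

test_that("draw count equals chains times retained iterations, reference fixed at 0", {
  net <- custom_net(star_trials(c(lagh = 0.5), 0.1))
  spec <- quick_spec(seed = 5, iterations = 2000, burn_in = 700, chains = 3)
  dr <- fit_continuous(net, spec)
  expect_identical(nrow(dr$d), 3L * (2000L - 700L))
  expect_true(all(dr$d[, "daily_somatropin"] == 0))
})

test_that("two identical arms give a posterior centred at zero", {
  net <- custom_net(star_trials(c(lagh = 0), 0.05))
  dr <- fit_continuous(net, quick_spec(seed = 2))
  expect_equal(median(contrast_draws(dr, "lagh", "daily_somatropin")), 0,
               tolerance = 0.01)
})

test_that("a three-trial star matches direct and indirect consistency sums", {
  effects <- c(lonapegsomatropin = 0.86, somatrogon = 1.57,
               somapacitan = 0.03)
  ses <- c(0.1276, 0.1480, 0.1722)
  net <- custom_net(star_trials(effects, ses))
  dr <- fit_continuous(net, quick_spec(seed = 31, iterations = 6000,
                                       burn_in = 1000))
  est <- summarize_effects(dr)
  pick <- function(a, b) est$point[est$treatment_a == a & est$treatment_b == b]
  expect_equal(pick("somatrogon", "daily_somatropin"), 1.57, tolerance = 0.02)
  expect_equal(pick("somatrogon", "lonapegsomatropin"), 1.57 - 0.86,
               tolerance = 0.02)
  expect_equal(pick("somatrogon", "somapacitan"), 1.57 - 0.03,
               tolerance = 0.02)
})

test_that("posterior medians agree with the inverse-variance oracle", {
  effects <- c(a = -0.4, b = 0.9, c = 0.25)
  ses <- c(0.15, 0.2, 0.12)
  trials <- star_trials(effects, ses, n = 80)
  net <- custom_net(trials)
  oracle <- frequentist_oracle(
    net, lapply(trials, trial_direct_estimate, outcome = "igf1_sds"))
  dr <- fit_continuous(net, quick_spec(seed = 8, iterations = 8000,
                                       burn_in = 2000))
  est <- summarize_effects(dr)
  merged <- merge(est, oracle, by = c("treatment_a", "treatment_b"))
  expect_equal(merged$point.x, merged$point.y, tolerance = 0.02)
  expect_equal(merged$cri_lower, merged$lower, tolerance = 0.03)
  expect_equal(merged$cri_upper, merged$upper, tolerance = 0.03)
})

test_that("relabeling the reference leaves pairwise estimates unchanged", {
  trials <- star_trials(c(lonapegsomatropin = 0.9, somatrogon = 0.2), c(0.2, 0.25))
  ids <- c("trial1", "trial2")
  net1 <- build_network(trials, "igf1_sds", scenario("custom", ids),
                        reference = "daily_somatropin")
  net2 <- build_network(trials, "igf1_sds", scenario("custom", ids),
                        reference = "lonapegsomatropin")
  e1 <- summarize_effects(fit_continuous(net1, quick_spec(seed = 3,
                                                          iterations = 8000,
                                                          burn_in = 2000)))
  e2 <- summarize_effects(fit_continuous(net2, quick_spec(seed = 4,
                                                          iterations = 8000,
                                                          burn_in = 2000)))
  m <- merge(e1, e2, by = c("treatment_a", "treatment_b"))
  expect_equal(m$point.x, m$point.y, tolerance = 0.02)
})

test_that("summaries enumerate ordered contrasts with exact antisymmetry", {
  withr::local_seed(21)
  d <- cbind(ref = 0, a = rnorm(500), b = rnorm(500), c = rnorm(500))
  dr <- fake_draws(d, reference = "ref")
  est <- summarize_effects(dr)
  expect_identical(nrow(est), 12L)
  for (i in seq_len(nrow(est))) {
    rev_row <- est[est$treatment_a == est$treatment_b[i] &
                   est$treatment_b == est$treatment_a[i], ]
    expect_equal(est$point[i], -rev_row$point)
    expect_equal(est$cri_lower[i], -rev_row$cri_upper)
  }
  expect_error(contrast_draws(dr, "a", "zzz"), "unknown treatment")
})

test_that("degenerate constant draws give a point mass summary", {
  d <- cbind(ref = numeric(100), a = rep(0.7, 100))
  est <- summarize_effects(fake_draws(d, reference = "ref"))
  row <- est[est$treatment_a == "a", ]
  expect_identical(row$point, 0.7)
  expect_identical(row$cri_lower, 0.7)
  expect_identical(row$cri_upper, 0.7)
})

test_that("odds-ratio antisymmetry is multiplicative", {
  net <- custom_net(list(binary_trial("t1", "lagh", 100, 10, 100, 5),
                         binary_trial("t2", "lagh", 150, 9, 150, 6)),
                    outcome = "sae")
  dr <- fit_binary(net, quick_spec("binary", seed = 44, iterations = 6000,
                                   burn_in = 2000))
  est <- summarize_effects(dr)
  ab <- est[est$treatment_a == "lagh", ]
  ba <- est[est$treatment_a == "daily_somatropin", ]
  expect_equal(ab$point * ba$point, 1)
  expect_true(all(est$point > 0) && all(est$cri_lower > 0))
})

test_that("a single binary trial recovers the sample odds ratio", {
  net <- custom_net(list(binary_trial("t1", "lagh", 100, 10, 100, 5)),
                    outcome = "sae")
  dr <- fit_binary(net, nma_model_spec("binary", seed = 15,
                                       iterations = 12000, burn_in = 3000))
  or <- median(exp(contrast_draws(dr, "lagh", "daily_somatropin")))
  # sample OR (10x95)/(5x90) = 2.11; posterior median sits near it at this n
  expect_equal(or, 2.11, tolerance = 0.15)
})

test_that("equal event proportions give an odds ratio near 1", {
  net <- custom_net(list(binary_trial("t1", "lagh", 200, 10, 200, 10)),
                    outcome = "sae")
  dr <- fit_binary(net, quick_spec("binary", seed = 16, iterations = 12000,
                                   burn_in = 3000))
  expect_equal(median(exp(contrast_draws(dr, "lagh", "daily_somatropin"))),
               1, tolerance = 0.1)
})

test_that("zero events in both arms of one trial stay finite", {
  net <- custom_net(list(binary_trial("z1", "lagh", 50, 0, 50, 0),
                         binary_trial("z2", "lagh", 80, 3, 80, 2)),
                    outcome = "sae")
  dr <- fit_binary(net, quick_spec("binary", seed = 17, iterations = 12000,
                                   burn_in = 3000))
  est <- summarize_effects(dr)
  expect_true(all(is.finite(est$point)))
  expect_true(all(is.finite(est$cri_lower) & est$cri_lower > 0))
})

test_that("the binomial-logit posterior matches an independent MCMC engine", {
  net <- custom_net(list(binary_trial("t1", "lagh", 100, 10, 100, 5)),
                    outcome = "sae")
  dr <- fit_binary(net, nma_model_spec("binary", seed = 18,
                                       iterations = 20000, burn_in = 5000))
  mine <- median(contrast_draws(dr, "lagh", "daily_somatropin"))
  model <- "model {
    r1 ~ dbin(p1, n1); logit(p1) <- mu + d
    r0 ~ dbin(p0, n0); logit(p0) <- mu
    mu ~ dnorm(0, 1e-4); d ~ dnorm(0, 1e-4)
  }"
  jm <- rjags::jags.model(
    textConnection(model), data = list(r1 = 10, n1 = 100, r0 = 5, n0 = 100),
    inits = list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 1),
    quiet = TRUE)
  update(jm, 4000, progress.bar = "none")
  ref <- median(as.matrix(rjags::coda.samples(jm, "d", 30000,
                                              progress.bar = "none")))
  expect_equal(mine, ref, tolerance = 0.05)
})

test_that("disconnected networks and bad inputs are refused", {
  t1 <- binary_trial("t1", "a", 10, 1, 10, 0, reference = "b")
  t2 <- binary_trial("t2", "c", 10, 1, 10, 0, reference = "d")
  net <- build_network(list(t1, t2), "sae",
                       scenario("custom", c("t1", "t2")), reference = "b")
  expect_error(fit_binary(net, quick_spec("binary")),
               class = "lagnma_feasibility_error")
  expect_error(fit_continuous(custom_net(star_trials(c(l = 1), 0.1)),
                              quick_spec("binary")),
               "outcome_kind")
})

test_that("the convergence gate trips on bad diagnostics", {
  net <- custom_net(star_trials(c(lagh = 0.5), 0.1))
  dr <- fit_continuous(net, quick_spec(seed = 1, iterations = 1200,
                                       burn_in = 400))
  dr$diagnostics$rhat[1] <- 1.2
  expect_error(lagnma:::check_convergence(dr),
               class = "lagnma_convergence_error")
  dr$diagnostics$rhat[1] <- 1.0
  dr$diagnostics$ess[1] <- 10
  expect_error(lagnma:::check_convergence(dr),
               class = "lagnma_convergence_error")
})

test_that("the oracle solves stars in closed form and flags singularity", {
  trials <- star_trials(c(lonapegsomatropin = 0.86, somatrogon = 1.57),
                        c(0.1276, 0.1480))
  net <- custom_net(trials)
  de <- lapply(trials, trial_direct_estimate, outcome = "igf1_sds")
  orc <- frequentist_oracle(net, de)
  row <- orc[orc$treatment_a == "somatrogon" &
             orc$treatment_b == "lonapegsomatropin", ]
  expect_equal(row$point, 0.71, tolerance = 1e-10)
  expect_equal(row$se, sqrt(0.1276^2 + 0.1480^2), tolerance = 1e-10)

  single <- star_trials(c(lonapegsomatropin = 0.9), 0.36225)
  orc1 <- frequentist_oracle(custom_net(single),
                             trial_direct_estimate(single[[1]], "igf1_sds"))
  expect_equal(orc1$point[orc1$treatment_a == "lonapegsomatropin"], 0.9)

  # an estimate on a detached pair cannot identify a 3-treatment network
  bad_net <- custom_net(star_trials(c(a = 1, b = 2), c(0.1, 0.1)))
  expect_error(
    frequentist_oracle(bad_net, data.frame(
      treatment_a = "a", treatment_b = "b", md = 1, se = 0.1)),
    "singular")
})

test_that("exported draws rebuild identical summaries", {
  net <- custom_net(star_trials(c(lagh = 0.4), 0.2))
  dr <- fit_continuous(net, quick_spec(seed = 77, iterations = 2000,
                                       burn_in = 600))
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws_csv(dr, f)
  back <- read_draws_csv(f, reference = "daily_somatropin", scale = "md")
  expect_equal(summarize_effects(back)$point, summarize_effects(dr)$point,
               tolerance = 1e-12)
})
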