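# One small S3 fit shared across the hurdle-related tests in this file.
s3_small_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sim <- simulate_trial(small_config(seed = 31))
      val <<- fit_s3(sim$data, mcmc = test_mcmc(seed = 8, iterations = 1200,
                                                burn_in = 600))
    }
    val
  }
})

test_that("WAIC matches its definition on hand-checkable inputs", {
  # constant log-likelihood: zero variance, WAIC = -2c
  expect_equal(compute_waic(matrix(c(-1.3, -1.3, -1.3), ncol = 1))$waic, 2.6)
  # 3 draws x 2 observations, brute-force check
  ll <- matrix(c(-1, -2, -1.5, -0.5, -0.7, -0.6), nrow = 3)
  w <- compute_waic(ll)
  bf <- waic_bruteforce(ll)
  expect_equal(w$waic, bf$waic, tolerance = 1e-12)
  expect_equal(w$p_waic, bf$p_waic, tolerance = 1e-12)
  # duplicating every observation doubles lppd and p_waic
  w2 <- compute_waic(cbind(ll, ll))
  expect_equal(w2$lppd, 2 * w$lppd)
  expect_equal(w2$p_waic, 2 * w$p_waic)
  expect_error(compute_waic(matrix(-1, nrow = 1)), "2 posterior draws")
})

test_that("WAIC equals the brute-force implementation on random matrices", {
  set.seed(7)
  for (r in 1:20) {
    ll <- matrix(rnorm(40 * 6, mean = -2), nrow = 40)
    expect_equal(compute_waic(ll)$waic, waic_bruteforce(ll)$waic,
                 tolerance = 1e-10)
  }
})

test_that("split R-hat separates converged, offset and degenerate chains", {
  set.seed(5)
  null_chains <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(trialcea:::split_rhat(null_chains), 1.01)
  offset_chains <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(trialcea:::split_rhat(offset_chains), 1.5)
  expect_true(is.na(trialcea:::split_rhat(cbind(rep(1, 100), rep(1, 100)))))
})

test_that("fit_s1 sanity: posterior mean of mu_e tracks the sample mean", {
  sim <- simulate_trial(small_config(seed = 13, n_per_arm = c(60, 50),
                                     miss = FALSE))
  out <- derive_outcomes(sim$data)
  fit <- fit_s1(out, mcmc = test_mcmc(seed = 3, iterations = 1500,
                                      burn_in = 500),
                cost_family = "normal", covariate_baseline = FALSE)
  for (a in 0:1) {
    dr <- fit$draws[fit$draws$arm == a, ]
    samp_mean <- mean(out$qaly[out$arm == a])
    mcse <- stats::sd(dr$mu_e) # posterior sd bounds the MC error comfortably
    expect_lt(abs(mean(dr$mu_e) - samp_mean), 3 * mcse)
  }
  d <- diagnose(fit)
  expect_s3_class(d, "fit_diagnostics")
  expect_true(all(d$rhat[is.finite(d$rhat)] < 1.1))
})

test_that("fit_s1 rejects degenerate all-missing outcomes", {
  sim <- simulate_trial(small_config(seed = 14, n_per_arm = c(20, 20)))
  out <- derive_outcomes(sim$data)
  out$total_cost <- NA_real_
  expect_error(fit_s1(out, mcmc = test_mcmc()), "no observed total costs")
})

test_that("the hurdle identity holds exactly per draw for every service and time", {
  fit <- s3_small_fit()
  cat3 <- catalog_of(fit$data)
  for (k in cat3$service) {
    for (t in 0:2) {
      lhs <- fit$draws[[paste0("mu_hru_", t, "_", k)]]
      rhs <- (1 - fit$draws[[paste0("pi_", k)]]) *
        fit$draws[[paste0("mu_pos_", t, "_", k)]]
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("S3 total-cost draws scale exactly with a global price multiplier", {
  fit <- s3_small_fit()
  d <- fit$data
  cat2 <- catalog_of(d)
  cat2$unit_price <- cat2$unit_price * 3
  d2 <- trial_data(tibble::as_tibble(d), schedule_of(d), cat2)
  fit2 <- fit_s3(d2, mcmc = test_mcmc(seed = 8, iterations = 1200,
                                      burn_in = 600))
  expect_equal(fit2$draws$mu_tc, fit$draws$mu_tc * 3, tolerance = 1e-9)
  expect_equal(fit2$draws$mu_e, fit$draws$mu_e, tolerance = 1e-12)
})

test_that("an all-zero service drives pi toward 1 and the marginal rate toward 0", {
  cfg <- small_config(seed = 41, n_per_arm = c(40, 35), miss = FALSE)
  cfg$pi_k <- c(1, 0.3, 0.3)
  sim <- simulate_trial(cfg)
  ws <- testthat::capture_warnings(
    fit <- fit_s3(sim$data, mcmc = test_mcmc(seed = 5, iterations = 800,
                                             burn_in = 400)))
  expect_match(ws, "structural zero", all = TRUE)
  expect_length(ws, 2)  # one per arm
  expect_gt(mean(fit$draws$pi_GP), 0.9)
  expect_lt(mean(abs(fit$draws$mu_hru_1_GP)), 0.1)
})

test_that("posterior predictive checks are calibrated on self-generated data", {
  # data drawn from the model family itself: normal QALYs, conditional
  # gamma total costs with log link
  set.seed(17)
  n <- 160
  u0 <- rnorm(n, 0.45, 0.2)
  e <- 0.5 + 0.4 * (u0 - mean(u0)) + rnorm(n, 0, 0.15)
  tc <- rgamma(n, shape = 3, rate = 3 / exp(log(2500) + 0.3 * (e - mean(e))))
  out <- tibble::tibble(id = 1:n, arm = rep(c(0, 1), each = n / 2),
                        u_0 = u0, qaly = e, total_cost = tc)
  fit <- fit_s1(out, mcmc = test_mcmc(seed = 2, iterations = 1500,
                                      burn_in = 500))
  pp <- posterior_predictive_check(fit, statistics = c("mean", "sd"),
                                   n_rep = 300, seed = 4)
  # model-consistent data: the large majority of checks non-extreme
  expect_gte(mean(pp$p_value >= 0.05 & pp$p_value <= 0.95), 0.75)
  expect_error(posterior_predictive_check(fit, statistics = "median"),
               "unknown statistic")
  # tie convention: a statistic identical in data and replicates gives p = 1
  expect_equal(trialcea:::ppc_pvalue(0, rep(0, 50)), 1)
})

test_that("the hurdle zero-proportion survives a posterior predictive check", {
  fit <- s3_small_fit()  # THERAP simulated with pi = 0.6
  pp <- posterior_predictive_check(fit, statistics = "prop_zero",
                                   n_rep = 300, seed = 6)
  therap <- pp[grepl("^THERAP", pp$outcome), ]
  expect_true(all(therap$p_value >= 0.025 & therap$p_value <= 0.975))
})
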