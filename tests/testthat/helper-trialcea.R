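# Shared fixtures, all built in code.

tiny_catalog <- function() {
  service_catalog(c("GP", "NURSE", "THERAP"), c(10, 5, 1))
}

# hand-built 4-individual, 3-visit panel with known missingness pattern
tiny_data <- function() {
  cat3 <- tiny_catalog()
  df <- tibble::tribble(
    ~id, ~arm, ~time, ~utility, ~GP, ~NURSE, ~THERAP,
    1,   0,    0,     0.5,      1,   2,      0,
    1,   0,    1,     0.6,      NA,  2,      0,
    1,   0,    2,     0.7,      2,   0,      0,
    2,   0,    0,     0.4,      0,   0,      0,
    2,   0,    1,     NA,       NA,  NA,     NA,
    2,   0,    2,     0.5,      0,   0,      0,
    3,   1,    0,     0.6,      3,   1,      2,
    3,   1,    1,     0.8,      2,   1,      1,
    3,   1,    2,     0.9,      1,   0,      2,
    4,   1,    0,     NA,       0,   0,      0,
    4,   1,    1,     0.3,      0,   0,      0,
    4,   1,    2,     0.2,      0,   0,      0
  )
  trial_data(df, schedule = schedule(c(0.5, 0.5)), catalog = cat3)
}

# quick simulation config: small n, 3 services, moderate missingness
small_config <- function(seed = 1, n_per_arm = c(40, 30),
                         miss = TRUE) {
  cat3 <- tiny_catalog()
  sim_config(
    n_per_arm = n_per_arm, schedule = schedule(c(0.5, 0.5)), catalog = cat3,
    pi_k = c(0.05, 0.3, 0.6),
    hru_mean = c(4, 3, 2), hru_sd = c(2, 1.5, 1), hru_ar = 0.5,
    u_mean = cbind(c(0.45, 0.5, 0.5), c(0.45, 0.55, 0.6)),
    u_sd = 0.25, u_ar = 0.5,
    miss_unit_utility = if (miss) c(0, 0.06, 0.05) else 0,
    miss_unit_hru = if (miss) c(0, 0.04, 0.03) else 0,
    miss_item = if (miss) c(0, 0.05, 0.04) else 0,
    mar_slope = if (miss) -1 else 0,
    seed = seed
  )
}

test_mcmc <- function(seed = 1, iterations = 2000, burn_in = 1000,
                      adapt = 300) {
  mcmc_config(chains = 2, iterations = iterations, burn_in = burn_in,
              adapt = adapt, seed = seed)
}

# independent dense-grid trapezoid integrator over the piecewise-linear
# utility trajectory (oracle for qaly())
qaly_bruteforce <- function(u, delta, n_grid = 2000) {
  tt <- c(0, cumsum(delta))
  total <- 0
  for (j in seq_along(delta)) {
    xs <- seq(tt[j], tt[j + 1], length.out = n_grid)
    ys <- stats::approx(tt, u, xout = xs)$y
    total <- total + sum((ys[-1] + ys[-n_grid]) / 2 * diff(xs))
  }
  total
}

# independent WAIC (plain formulas, no log-sum-exp rearrangement)
waic_bruteforce <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p), lppd = lppd, p_waic = p)
}

# synthetic aligned arm-level draws for the economics layer
fake_arm_draws <- function(n = 500, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    arm = rep(c(0, 1), each = n),
    mu_e = c(rnorm(n, 0.49, 0.02), rnorm(n, 0.60, 0.02)),
    mu_tc = c(rnorm(n, 2600, 150), rnorm(n, 2500, 150))
  )
}
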