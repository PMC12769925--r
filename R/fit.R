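# Fitting layer: each strategy is fitted separately per arm, with missing
# outcomes left as NA so the sampler treats them as unknowns (the Bayesian
# "ALL" handling). Costs are rescaled to thousands of currency units before
# fitting and rescaled back in all reported draws.

COST_SCALE <- 1000

offset_zero_costs <- function(x, eps = 0.01) {
  n_off <- sum(x == 0, na.rm = TRUE)
  x[!is.na(x) & x == 0] <- eps
  list(x = x, n_offset = n_off)
}

new_cea_fit <- function(strategy, draws, arms, data, mcmc, priors, extra = list()) {
  structure(c(list(strategy = strategy, draws = draws, arms = arms,
                   data = data, mcmc = mcmc, priors = priors), extra),
            class = c(paste0("cea_fit_", strategy), "cea_fit"))
}

#' @export
print.cea_fit <- function(x, ...) {
  cat("<cea_fit> strategy", toupper(x$strategy),
      "-", nrow(x$draws) / 2, "draws per arm,",
      x$mcmc$chains, "chains\n")
  s <- dplyr::summarise(
    dplyr::group_by(x$draws, .data$arm),
    mu_e = mean(.data$mu_e), mu_tc = mean(.data$mu_tc), .groups = "drop")
  print(s)
  invisible(x)
}

# pull loglik columns (observed entries only) out of an mcmc.list matrix
extract_loglik <- function(mat, prefix, obs_idx) {
  cols <- paste0(prefix, "[", obs_idx, "]")
  mat[, cols, drop = FALSE]
}

samples_matrix <- function(samples) {
  do.call(rbind, lapply(samples, as.matrix))
}

drop_ll <- function(samples) {
  keep <- !grepl("^ll\\.", coda::varnames(samples))
  samples[, keep, drop = FALSE]
}

#' Fit the aggregated model: total costs and QALYs (strategy S1)
#'
#' Per arm, a marginal normal model for the QALY `e_i` (adjusted for
#' baseline utility, itself modelled marginally so missing baselines are
#' handled) and a conditional cost model for `tc_i` given `e_i` — gamma
#' with log link by default, with lognormal and normal alternatives for
#' model comparison by WAIC. Missing QALYs and totals are sampled within
#' MCMC. Observed zero totals are offset by 0.01 currency units before a
#' gamma/lognormal fit (count recorded in the fit object).
#'
#' @param outcomes Per-individual outcomes from [derive_outcomes()] or
#'   [apply_strategy()]: columns `id`, `arm`, `u_0`, `qaly`, `total_cost`.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param cost_family `"gamma"` (default), `"lognormal"` or `"normal"`.
#' @param covariate_baseline Adjust the QALY model for baseline utility?
#' @param monitor_loglik Record pointwise log-likelihoods (for [compute_waic()]).
#' @return A `cea_fit` object; `$draws` holds per-draw `mu_e`, `mu_tc` by
#'   arm, `$arms[[a]]$samples` the full parameter chains.
#' @export
fit_s1 <- function(outcomes, priors = prior_spec(), mcmc = mcmc_config(),
                   cost_family = c("gamma", "lognormal", "normal"),
                   covariate_baseline = TRUE, monitor_loglik = FALSE) {
  cost_family <- match.arg(cost_family)
  stopifnot(all(c("id", "arm", "u_0", "qaly", "total_cost") %in% names(outcomes)))
  model <- jags_model_s1(cost_family, covariate_baseline)

  fit_arm <- function(a) {
    oa <- outcomes[outcomes$arm == a, ]
    e <- oa$qaly
    tc <- oa$total_cost
    if (all(is.na(tc))) {
      stop("arm ", a, ": no observed total costs to fit", call. = FALSE)
    }
    if (all(is.na(e))) {
      stop("arm ", a, ": no observed QALYs to fit", call. = FALSE)
    }
    off <- offset_zero_costs(tc)
    tc_s <- off$x / COST_SCALE
    dat <- c(list(n = nrow(oa), e = e, tc = tc_s,
                  ebar = mean(e, na.rm = TRUE)),
             prior_data(priors))
    if (covariate_baseline) {
      dat$u0 <- oa$u_0
      dat$u0bar <- mean(oa$u_0, na.rm = TRUE)
    }
    if (cost_family == "gamma") dat$shape.rate <- dat$shape.rate else dat$shape.rate <- NULL
    monitors <- c("mu.e", "mu.tc", "alpha0", "beta0", "beta1", "sd.e",
                  if (covariate_baseline) c("alpha1", "mu.u0", "sd.u0"),
                  if (cost_family == "gamma") "sh.tc" else "sd.tc",
                  if (monitor_loglik) c("ll.e", "ll.tc"))
    smp <- run_jags(model, dat, monitors, mcmc, seed_offset = 101L * (a + 1L))
    loglik <- NULL
    if (monitor_loglik) {
      m <- samples_matrix(smp)
      loglik <- list(qaly = extract_loglik(m, "ll.e", which(!is.na(e))),
                     cost = extract_loglik(m, "ll.tc", which(!is.na(tc))))
      smp <- drop_ll(smp)
    }
    list(samples = smp, loglik = loglik, n = nrow(oa),
         n_offset = off$n_offset)
  }

  arms <- list(`0` = fit_arm(0), `1` = fit_arm(1))
  draws <- purrr::map_dfr(c(0, 1), function(a) {
    d <- draws_tibble(arms[[as.character(a)]]$samples)
    tibble::tibble(chain = d$chain, iteration = d$iteration, arm = a,
                   mu_e = d[["mu.e"]], mu_tc = d[["mu.tc"]] * COST_SCALE)
  })
  new_cea_fit("s1", draws, arms, outcomes, mcmc, priors,
              extra = list(cost_family = cost_family,
                           covariate_baseline = covariate_baseline))
}

#' Fit the longitudinal model: costs and utilities at each time (strategy S2)
#'
#' Per arm and follow-up visit `j`, a normal model for utility given the
#' previous utility and the contemporaneous per-time cost, and a gamma
#' (log link; normal alternative) model for the per-time cost given the
#' previous visit's utility and cost; baseline utility and cost are
#' modelled marginally. Missing utilities and per-time costs are sampled
#' within MCMC. Marginal means per time are recovered by averaging the
#' predicted means over the sample and assembled into `mu_e` (trapezoid
#' over the schedule) and `mu_tc` (sum over follow-up visits).
#'
#' @param data A [trial_data()] object (source of utilities and schedule).
#' @param outcomes Optional outcomes from [apply_strategy()]; defaults to
#'   the untouched `"ALL"` derivation of `data`.
#' @inheritParams fit_s1
#' @param cost_family `"gamma"` (default) or `"normal"`.
#' @return A `cea_fit` object; `$draws` additionally holds per-time
#'   `mu_u_<t>` and `mu_c_<t>` columns.
#' @export
fit_s2 <- function(data, outcomes = NULL, priors = prior_spec(),
                   mcmc = mcmc_config(), cost_family = c("gamma", "normal"),
                   monitor_loglik = FALSE) {
  cost_family <- match.arg(cost_family)
  sched <- schedule_of(data)
  Jp1 <- nrow(sched)
  if (is.null(outcomes)) outcomes <- derive_outcomes(data)
  model <- jags_model_s2(cost_family)

  fit_arm <- function(a) {
    oa <- outcomes[outcomes$arm == a, ]
    oa <- oa[order(oa$id), ]
    u <- as.matrix(oa[paste0("u_", sched$time)])
    cmat <- as.matrix(oa[paste0("cost_", sched$time)])
    if (all(is.na(cmat[, -1]))) {
      stop("arm ", a, ": no observed follow-up costs to fit", call. = FALSE)
    }
    off <- offset_zero_costs(cmat)
    cs <- off$x / COST_SCALE
    colmean0 <- function(m) {
      v <- suppressWarnings(colMeans(m, na.rm = TRUE))
      ifelse(is.finite(v), v, 0)
    }
    dat <- c(list(n = nrow(oa), Jp1 = Jp1, u = u, c = cs,
                  ubar = colmean0(u), cbar = colmean0(cs),
                  delta = schedule_delta(sched)),
             prior_data(priors))
    if (cost_family != "gamma") dat$shape.rate <- NULL
    monitors <- c("mu.e", "mu.tc", "mu.u", "mu.c", "a0", "a1", "a2",
                  "b0", "b1", "b2", "sd.u", "mu.u0", "sd.u0",
                  if (cost_family == "gamma") "sh.c" else "sd.c",
                  if (monitor_loglik) c("ll.u", "ll.c"))
    smp <- run_jags(model, dat, monitors, mcmc, seed_offset = 211L * (a + 1L))
    loglik <- NULL
    if (monitor_loglik) {
      m <- samples_matrix(smp)
      obs_u <- which(!is.na(u))
      obs_c <- which(!is.na(cmat))
      idx2 <- function(w) {
        paste0("[", (w - 1L) %% nrow(u) + 1L, ",", (w - 1L) %/% nrow(u) + 1L, "]")
      }
      loglik <- list(utility = m[, paste0("ll.u", idx2(obs_u)), drop = FALSE],
                     cost = m[, paste0("ll.c", idx2(obs_c)), drop = FALSE])
      smp <- drop_ll(smp)
    }
    list(samples = smp, loglik = loglik, n = nrow(oa),
         n_offset = off$n_offset)
  }

  arms <- list(`0` = fit_arm(0), `1` = fit_arm(1))
  draws <- purrr::map_dfr(c(0, 1), function(a) {
    d <- draws_tibble(arms[[as.character(a)]]$samples)
    out <- tibble::tibble(chain = d$chain, iteration = d$iteration, arm = a,
                          mu_e = d[["mu.e"]],
                          mu_tc = d[["mu.tc"]] * COST_SCALE)
    for (j in seq_len(Jp1)) {
      out[[paste0("mu_u_", sched$time[j])]] <- d[[paste0("mu.u[", j, "]")]]
      out[[paste0("mu_c_", sched$time[j])]] <-
        d[[paste0("mu.c[", j, "]")]] * COST_SCALE
    }
    out
  })
  new_cea_fit("s2", draws, arms, data, mcmc, priors,
              extra = list(cost_family = cost_family, outcomes = outcomes))
}

# classify structural-zero status from an observed profile:
# 0 = any positive observation, 1 = complete all-zero profile, NA otherwise
observed_structural_status <- function(hru_ik) {
  if (any(!is.na(hru_ik) & hru_ik > 0)) return(0)
  if (!anyNA(hru_ik) && all(hru_ik == 0)) return(1)
  NA_real_
}

#' Fit the disaggregated hurdle model: per-service HRU and utilities (S3)
#'
#' Per arm and service, a two-part (hurdle) model: a Bernoulli indicator of
#' a structural zero — zero use at every visit — with logistic regression
#' on centred baseline utility, and a normal model for usage among
#' potentially non-structural individuals conditioned on the previous
#' visit's utility and usage. Individuals whose observed profile is
#' all-zero but incomplete have a latent indicator updated within MCMC
#' (a high-precision spike at zero represents the point mass); missing
#' usage items are likewise sampled. Per draw, the marginal usage rate
#' combines exactly as `mu_hru = (1 - pi) * mu_pos`, is priced into
#' per-service costs and summed over services and follow-up visits into
#' `mu_tc`. Utilities are modelled longitudinally as in [fit_s2()].
#'
#' @param data A [trial_data()] object.
#' @inheritParams fit_s1
#' @return A `cea_fit` object; `$draws` additionally holds `pi_<service>`,
#'   `mu_pos_<t>_<service>` and `mu_hru_<t>_<service>` columns.
#' @export
fit_s3 <- function(data, priors = prior_spec(), mcmc = mcmc_config()) {
  sched <- schedule_of(data)
  cat <- catalog_of(data)
  Jp1 <- nrow(sched)
  K <- nrow(cat)
  model <- jags_model_s3()

  fit_arm <- function(a) {
    df <- tibble::as_tibble(data)
    df <- df[df$arm == a, ]
    df <- df[order(df$id, df$time), ]
    ids <- unique(df$id)
    n <- length(ids)
    u <- matrix(df$utility, n, Jp1, byrow = TRUE)
    hru <- array(NA_real_, c(n, Jp1, K))
    for (k in seq_len(K)) {
      hru[, , k] <- matrix(df[[cat$service[k]]], n, Jp1, byrow = TRUE)
    }
    dobs <- matrix(NA_real_, n, K)
    for (k in seq_len(K)) {
      dobs[, k] <- apply(hru[, , k, drop = FALSE], 1, observed_structural_status)
    }
    m <- integer(K)
    idx <- matrix(1L, n, K)
    for (k in seq_len(K)) {
      w <- which(is.na(dobs[, k]) | dobs[, k] == 0)
      if (length(w) == 0L) {
        warning("arm ", a, ", service ", cat$service[k],
                ": every profile is a complete structural zero; ",
                "continuous component degenerate", call. = FALSE)
        w <- 1L  # harmless: spike likelihood on an observed-zero profile
      }
      m[k] <- length(w)
      idx[seq_along(w), k] <- w
    }
    hbar <- matrix(0, Jp1, K)
    for (k in seq_len(K)) {
      for (j in seq_len(Jp1)) {
        v <- hru[idx[seq_len(m[k]), k], j, k]
        if (any(!is.na(v))) hbar[j, k] <- mean(v, na.rm = TRUE)
      }
    }
    ubar <- suppressWarnings(colMeans(u, na.rm = TRUE))
    ubar <- ifelse(is.finite(ubar), ubar, 0)
    dat <- c(list(n = n, Jp1 = Jp1, K = K, u = u, hru = hru, d = dobs,
                  m = m, idx = idx, delta = schedule_delta(sched),
                  price = cat$unit_price, spike = 1e6,
                  ubar = ubar, hbar = hbar,
                  u0bar = mean(u[, 1], na.rm = TRUE)),
             prior_data(priors))
    dat$shape.rate <- NULL
    monitors <- c("mu.e", "mu.tc", "mu.u", "mu.c", "pi.k", "mu.pos",
                  "mu.hru", "g0", "g1", "a0", "a1", "b0", "sd.h", "sd.u",
                  "mu.u0", "sd.u0")
    smp <- run_jags(model, dat, monitors, mcmc, seed_offset = 307L * (a + 1L))
    list(samples = smp, n = n, n_offset = 0L)
  }

  arms <- list(`0` = fit_arm(0), `1` = fit_arm(1))
  draws <- purrr::map_dfr(c(0, 1), function(a) {
    d <- draws_tibble(arms[[as.character(a)]]$samples)
    out <- tibble::tibble(chain = d$chain, iteration = d$iteration, arm = a,
                          mu_e = d[["mu.e"]], mu_tc = d[["mu.tc"]])
    for (j in seq_len(Jp1)) {
      out[[paste0("mu_u_", sched$time[j])]] <- d[[paste0("mu.u[", j, "]")]]
      out[[paste0("mu_c_", sched$time[j])]] <- d[[paste0("mu.c[", j, "]")]]
    }
    for (k in seq_len(K)) {
      out[[paste0("pi_", cat$service[k])]] <- d[[paste0("pi.k[", k, "]")]]
      for (j in seq_len(Jp1)) {
        out[[paste0("mu_pos_", sched$time[j], "_", cat$service[k])]] <-
          d[[paste0("mu.pos[", j, ",", k, "]")]]
        out[[paste0("mu_hru_", sched$time[j], "_", cat$service[k])]] <-
          d[[paste0("mu.hru[", j, ",", k, "]")]]
      }
    }
    out
  })
  new_cea_fit("s3", draws, arms, data, mcmc, priors)
}
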