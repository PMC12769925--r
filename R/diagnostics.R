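# Convergence diagnostics, WAIC and posterior predictive checks.

# split-R-hat for a (iterations x chains) matrix of draws of one parameter:
# each chain is split in half and the usual potential-scale-reduction
# statistic computed over the split chains.
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(ch) {
    cbind(x[seq_len(half), ch], x[seq.int(n - half + 1L, n), ch])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' MCMC convergence diagnostics
#'
#' Split potential-scale-reduction factor (R-hat) and effective sample size
#' for every monitored parameter in every arm. The fit is flagged
#' converged when all finite R-hat values are below `threshold`; parameters
#' whose chains are constant (zero within-chain variance) yield `NA` R-hat
#' and are reported as degenerate rather than failing the flag.
#'
#' @param fit A `cea_fit` object.
#' @param threshold Convergence threshold on R-hat (default 1.05).
#' @return A tibble of class `fit_diagnostics` with columns `arm`,
#'   `parameter`, `rhat`, `ess`; attributes `converged` (logical) and
#'   `degenerate` (parameter names with undefined R-hat).
#' @export
diagnose <- function(fit, threshold = 1.05) {
  stopifnot(inherits(fit, "cea_fit"))
  out <- purrr::map_dfr(names(fit$arms), function(a) {
    smp <- fit$arms[[a]]$samples
    if (length(smp) < 2L) stop("diagnostics need at least 2 chains", call. = FALSE)
    pars <- coda::varnames(smp)
    ess <- coda::effectiveSize(smp)
    rhat <- vapply(pars, function(p) {
      x <- vapply(smp, function(ch) as.numeric(ch[, p]),
                  numeric(nrow(smp[[1]])))
      split_rhat(x)
    }, numeric(1))
    tibble::tibble(arm = a, parameter = pars,
                   rhat = unname(rhat), ess = unname(ess[pars]))
  })
  degen <- out$parameter[!is.finite(out$rhat)]
  converged <- all(out$rhat[is.finite(out$rhat)] < threshold)
  structure(out, converged = converged, degenerate = unique(degen),
            class = c("fit_diagnostics", class(tibble::tibble())))
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 (lppd - p_waic)` where `lppd` is the sum over observations of
#' the log of the posterior-mean likelihood, and the effective number of
#' parameters `p_waic` is the sum of posterior variances of the pointwise
#' log-likelihood.
#'
#' @param loglik Matrix of pointwise log-likelihoods, draws in rows,
#'   observations in columns (as stored under `$arms[[a]]$loglik` by the
#'   fitters when `monitor_loglik = TRUE`).
#' @return A list of class `trialcea_waic`: `waic`, `lppd`, `p_waic`,
#'   `elpd`, `n_obs`.
#' @export
compute_waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2L) {
    stop("WAIC needs at least 2 posterior draws", call. = FALSE)
  }
  lppd <- sum(apply(loglik, 2, log_mean_exp))
  p_waic <- sum(apply(loglik, 2, stats::var))
  elpd <- lppd - p_waic
  structure(list(waic = -2 * elpd, lppd = lppd, p_waic = p_waic,
                 elpd = elpd, n_obs = ncol(loglik)),
            class = "trialcea_waic")
}

#' @export
print.trialcea_waic <- function(x, ...) {
  cat(sprintf("WAIC %.2f (lppd %.2f, p_waic %.2f, n = %d)\n",
              x$waic, x$lppd, x$p_waic, x$n_obs))
  invisible(x)
}

ppc_stats <- list(
  mean = function(x) mean(x),
  sd = function(x) stats::sd(x),
  prop_zero = function(x) mean(x == 0)
)

ppc_pvalue <- function(obs_stat, rep_stats) mean(rep_stats >= obs_stat)

#' Posterior predictive checks
#'
#' Replicate datasets are generated from a thinned subset of the posterior
#' draws and a chosen summary statistic is compared with its observed
#' value; the reported p-value is the fraction of replicates whose
#' statistic is greater than or equal to the observed one (so a statistic
#' identically equal in data and replicates gives p = 1). Values near 0 or
#' 1 indicate that the model fails to reproduce that aspect of the data.
#'
#' Replication schemes by strategy: for S1 the full generative chain
#' (baseline utility, QALY, total cost) is replayed per draw; for S3 each
#' service is replicated from its hurdle — a Bernoulli structural zero at
#' rate `pi_k`, otherwise a normal draw around the marginal nonzero rate.
#' For S2 per-time costs are replicated around the marginal per-time mean.
#' The S2/S3 schemes marginalise over individual covariates, which makes
#' the `sd` statistic conservative there; `mean` and `prop_zero` are the
#' recommended checks at those levels.
#'
#' @param fit A `cea_fit` object.
#' @param statistics Any of `"mean"`, `"sd"`, `"prop_zero"`.
#' @param n_rep Number of replicate datasets (posterior draws used).
#' @param seed Seed for the replicate generation.
#' @return A tibble with columns `arm`, `outcome`, `statistic`, `observed`,
#'   `p_value`.
#' @export
posterior_predictive_check <- function(fit,
                                       statistics = c("mean", "sd", "prop_zero"),
                                       n_rep = 400, seed = 1) {
  stopifnot(inherits(fit, "cea_fit"))
  bad <- setdiff(statistics, names(ppc_stats))
  if (length(bad)) {
    stop("unknown statistic(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  UseMethod("posterior_predictive_check")
}

thin_draws <- function(mat, n_rep) {
  idx <- unique(round(seq(1, nrow(mat), length.out = min(n_rep, nrow(mat)))))
  mat[idx, , drop = FALSE]
}

check_one <- function(obs, rep_mat, statistics, arm, outcome) {
  obs <- obs[!is.na(obs)]
  purrr::map_dfr(statistics, function(s) {
    f <- ppc_stats[[s]]
    rep_stats <- apply(rep_mat, 1, f)
    tibble::tibble(arm = arm, outcome = outcome, statistic = s,
                   observed = f(obs), p_value = ppc_pvalue(f(obs), rep_stats))
  })
}

#' @export
posterior_predictive_check.cea_fit_s1 <- function(fit,
    statistics = c("mean", "sd", "prop_zero"), n_rep = 400, seed = 1) {
  purrr::map_dfr(c(0, 1), function(a) {
    arm <- fit$arms[[as.character(a)]]
    mat <- thin_draws(samples_matrix(arm$samples), n_rep)
    oa <- fit$data[fit$data$arm == a, ]
    n <- nrow(oa)
    cov_b <- isTRUE(fit$covariate_baseline)
    reps_e <- matrix(NA_real_, nrow(mat), n)
    reps_tc <- matrix(NA_real_, nrow(mat), n)
    ebar <- mean(oa$qaly, na.rm = TRUE)
    u0bar <- mean(oa$u_0, na.rm = TRUE)
    for (r in seq_len(nrow(mat))) {
      p <- mat[r, ]
      u0 <- if (cov_b) stats::rnorm(n, p["mu.u0"], p["sd.u0"]) else numeric(n)
      phi_e <- p["alpha0"] + if (cov_b) p["alpha1"] * (u0 - u0bar) else 0
      e <- stats::rnorm(n, phi_e, p["sd.e"])
      lin <- p["beta0"] + p["beta1"] * (e - ebar)
      tc <- switch(fit$cost_family,
        gamma = stats::rgamma(n, shape = p["sh.tc"],
                              rate = p["sh.tc"] / exp(lin)),
        lognormal = stats::rlnorm(n, lin, p["sd.tc"]),
        normal = stats::rnorm(n, lin, p["sd.tc"]))
      reps_e[r, ] <- e
      reps_tc[r, ] <- tc * COST_SCALE
    }
    dplyr::bind_rows(
      check_one(oa$qaly, reps_e, statistics, a, "qaly"),
      check_one(oa$total_cost, reps_tc, statistics, a, "total_cost"))
  })
}

#' @export
posterior_predictive_check.cea_fit_s2 <- function(fit,
    statistics = c("mean", "sd", "prop_zero"), n_rep = 400, seed = 1) {
  sched <- schedule_of(fit$data)
  outcomes <- fit$outcomes
  purrr::map_dfr(c(0, 1), function(a) {
    arm <- fit$arms[[as.character(a)]]
    mat <- thin_draws(samples_matrix(arm$samples), n_rep)
    oa <- outcomes[outcomes$arm == a, ]
    n <- nrow(oa)
    purrr::map_dfr(seq_len(nrow(sched)), function(j) {
      obs <- oa[[paste0("cost_", sched$time[j])]]
      reps <- matrix(NA_real_, nrow(mat), n)
      for (r in seq_len(nrow(mat))) {
        p <- mat[r, ]
        mu <- p[paste0("mu.c[", j, "]")]
        reps[r, ] <- if (fit$cost_family == "gamma") {
          sh <- p[paste0("sh.c[", j, "]")]
          stats::rgamma(n, shape = sh, rate = sh / mu)
        } else {
          stats::rnorm(n, mu, p[paste0("sd.c[", j, "]")])
        }
      }
      check_one(obs, reps * COST_SCALE, statistics, a,
                paste0("cost_", sched$time[j]))
    })
  })
}

#' @export
posterior_predictive_check.cea_fit_s3 <- function(fit,
    statistics = c("mean", "sd", "prop_zero"), n_rep = 400, seed = 1) {
  sched <- schedule_of(fit$data)
  cat <- catalog_of(fit$data)
  df <- tibble::as_tibble(fit$data)
  purrr::map_dfr(c(0, 1), function(a) {
    arm <- fit$arms[[as.character(a)]]
    mat <- thin_draws(samples_matrix(arm$samples), n_rep)
    da <- df[df$arm == a, ]
    n <- length(unique(da$id))
    purrr::map_dfr(seq_len(nrow(cat)), function(k) {
      purrr::map_dfr(seq_len(nrow(sched)), function(j) {
        obs <- da[[cat$service[k]]][da$time == sched$time[j]]
        reps <- matrix(NA_real_, nrow(mat), n)
        for (r in seq_len(nrow(mat))) {
          p <- mat[r, ]
          dz <- stats::rbinom(n, 1, p[paste0("pi.k[", k, "]")])
          pos <- stats::rnorm(n, p[paste0("mu.pos[", j, ",", k, "]")],
                              p[paste0("sd.h[", j, ",", k, "]")])
          reps[r, ] <- ifelse(dz == 1, 0, pos)
        }
        check_one(obs, reps, statistics, a,
                  paste0(cat$service[k], "_", sched$time[j]))
      })
    })
  })
}
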