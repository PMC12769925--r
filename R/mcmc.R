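#' MCMC run configuration
#'
#' Defaults mirror a conventional production run for these models: 2 chains
#' of 20,000 iterations each with the first 10,000 discarded as burn-in,
#' leaving 20,000 draws for inference. Reduced profiles (e.g. 2 x 2,000
#' with burn-in 1,000) are adequate for simulation experiments and are used
#' throughout the test-suite problem sizes.
#'
#' @param chains Number of chains (at least 2, so convergence can be
#'   diagnosed).
#' @param iterations Total iterations per chain, including burn-in.
#' @param burn_in Iterations discarded per chain.
#' @param adapt Sampler adaptation steps before burn-in.
#' @param seed Integer seed; all chain RNGs are derived from it.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 2L, iterations = 20000L, burn_in = 10000L,
                        adapt = 500L, seed = 1L) {
  if (chains < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (burn_in >= iterations) {
    stop("`burn_in` must be smaller than `iterations`", call. = FALSE)
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 adapt = as.integer(adapt),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Weakly informative prior hyperparameters
#'
#' Normal(0, `coef_sd`^2) on every regression coefficient (on the link
#' scale), half-Normal(0, `sd_scale`) on normal-likelihood standard
#' deviations, Exponential(`shape_rate`) on gamma shapes. Cost outcomes are
#' rescaled internally to thousands of currency units before fitting, so a
#' single scale works across utilities, usage counts and costs; results are
#' reported back on the original scale.
#'
#' @param coef_sd Prior standard deviation of regression coefficients.
#' @param sd_scale Scale of the half-normal prior on standard deviations.
#' @param shape_rate Rate of the exponential prior on gamma shapes.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(coef_sd = 10, sd_scale = 10, shape_rate = 0.1) {
  if (coef_sd <= 0 || sd_scale <= 0 || shape_rate <= 0) {
    stop("prior scales must be positive", call. = FALSE)
  }
  structure(list(coef_sd = coef_sd, sd_scale = sd_scale,
                 shape_rate = shape_rate),
            class = "prior_spec")
}

prior_data <- function(priors) {
  list(prec.coef = 1 / priors$coef_sd^2,
       prec.sd = 1 / priors$sd_scale^2,
       shape.rate = priors$shape_rate)
}

# Run one JAGS model: returns a coda::mcmc.list of the monitored nodes.
run_jags <- function(model_string, data, monitors, mcmc, inits = NULL,
                     seed_offset = 0L) {
  seeds <- mcmc$seed + seed_offset + seq_len(mcmc$chains)
  init_list <- lapply(seeds, function(s) {
    c(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s),
      if (is.null(inits)) list() else inits)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = init_list, n.chains = mcmc$chains,
                          n.adapt = mcmc$adapt, quiet = TRUE)
  stats::update(jm, n.iter = mcmc$burn_in, progress.bar = "none")
  rjags::coda.samples(jm, variable.names = monitors,
                      n.iter = mcmc$iterations - mcmc$burn_in,
                      progress.bar = "none")
}

# mcmc.list -> tibble with chain/iteration columns
draws_tibble <- function(samples) {
  purrr::imap_dfr(seq_along(samples), function(ch, i) {
    m <- as.matrix(samples[[ch]])
    out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
    dplyr::bind_cols(tibble::tibble(chain = ch, iteration = seq_len(nrow(m))),
                     out)
  })
}
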