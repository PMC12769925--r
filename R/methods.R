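#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a fitted strategy
#'
#' One row per derived quantity and arm: posterior mean, standard
#' deviation, and equal-tailed 95% credible interval.
#'
#' @param x A `cea_fit` object.
#' @param conf_level Credible level (default 0.95, equal-tailed).
#' @param ... Unused.
#' @return A tibble with columns `term`, `arm`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy cea_fit
#' @export
tidy.cea_fit <- function(x, conf_level = 0.95, ...) {
  a2 <- (1 - conf_level) / 2
  long <- tidyr::pivot_longer(x$draws,
                              cols = -c("chain", "iteration", "arm"),
                              names_to = "term", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$term, .data$arm),
    estimate = mean(.data$value),
    std.error = stats::sd(.data$value),
    conf.low = stats::quantile(.data$value, a2, names = FALSE),
    conf.high = stats::quantile(.data$value, 1 - a2, names = FALSE),
    .groups = "drop"
  )
}

#' One-line fit summary
#'
#' @param x A `cea_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: strategy, sample size, chains, kept draws per
#'   arm, worst R-hat, smallest effective sample size, convergence flag,
#'   count of zero-cost offsets applied before gamma fitting.
#' @method glance cea_fit
#' @export
glance.cea_fit <- function(x, ...) {
  d <- diagnose(x)
  tibble::tibble(
    strategy = toupper(x$strategy),
    n = sum(vapply(x$arms, function(a) a$n, numeric(1))),
    chains = x$mcmc$chains,
    draws_per_arm = x$mcmc$chains * (x$mcmc$iterations - x$mcmc$burn_in),
    max_rhat = max(d$rhat, na.rm = TRUE),
    min_ess = min(d$ess, na.rm = TRUE),
    converged = attr(d, "converged"),
    n_zero_offset = sum(vapply(x$arms, function(a) a$n_offset, numeric(1)))
  )
}
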