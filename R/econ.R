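# Cost-effectiveness layer: per-draw increments, ICER, CEP, CEAC.

#' Per-draw increments of mean QALYs and total costs
#'
#' Pairs posterior draws of the arm-level marginal means by draw index and
#' forms `delta_e = mu_e(intervention) - mu_e(control)` and likewise
#' `delta_tc`: positive `delta_e` favours the intervention. (The threshold
#' and acceptability machinery below assumes this orientation.)
#'
#' @param x A `cea_fit` object, or a data frame with columns `arm` (0/1),
#'   `mu_e`, `mu_tc` and equal draw counts per arm, aligned by row order
#'   within arm.
#' @return A tibble of class `cea_increments` with columns `draw`,
#'   `delta_e`, `delta_tc`.
#' @export
increments <- function(x) {
  df <- if (inherits(x, "cea_fit")) x$draws else tibble::as_tibble(x)
  stopifnot(all(c("arm", "mu_e", "mu_tc") %in% names(df)))
  d0 <- df[df$arm == 0, ]
  d1 <- df[df$arm == 1, ]
  if (nrow(d0) != nrow(d1) || nrow(d0) == 0L) {
    stop("draw counts must be equal and positive in both arms", call. = FALSE)
  }
  out <- tibble::tibble(draw = seq_len(nrow(d0)),
                        delta_e = d1$mu_e - d0$mu_e,
                        delta_tc = d1$mu_tc - d0$mu_tc)
  class(out) <- c("cea_increments", class(out))
  out
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = mean(delta_tc) / mean(delta_e)` over the posterior draws.
#'
#' @param inc A [increments()] tibble.
#' @return A single number (currency per QALY).
#' @export
icer <- function(inc) {
  de <- mean(inc$delta_e)
  if (de == 0) {
    stop("ICER undefined: mean incremental effectiveness is zero",
         call. = FALSE)
  }
  mean(inc$delta_tc) / de
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `k`, the probability of
#' cost-effectiveness is the fraction of posterior draws whose incremental
#' net benefit `k * delta_e - delta_tc` is strictly positive — the
#' fraction of the cost-effectiveness plane cloud lying strictly below the
#' threshold line. At `k = 0` this is exactly `P(delta_tc < 0)`; as `k`
#' grows it approaches `P(delta_e > 0)`.
#'
#' @param inc A [increments()] tibble.
#' @param k_grid Strictly increasing non-negative willingness-to-pay grid,
#'   currency per QALY (default 0 to 10,000 in steps of 100).
#' @return A tibble of class `cea_ceac` with columns `k`, `probability`.
#' @export
ceac <- function(inc, k_grid = seq(0, 10000, by = 100)) {
  if (length(k_grid) == 0L) stop("`k_grid` must be non-empty", call. = FALSE)
  if (is.unsorted(k_grid, strictly = TRUE)) {
    stop("`k_grid` must be strictly increasing", call. = FALSE)
  }
  prob <- vapply(k_grid, function(k) {
    mean(k * inc$delta_e - inc$delta_tc > 0)
  }, numeric(1))
  out <- tibble::tibble(k = k_grid, probability = prob)
  class(out) <- c("cea_ceac", class(out))
  out
}

#' Cost-effectiveness plane summary
#'
#' The joint posterior cloud of `(delta_e, delta_tc)` with quadrant labels,
#' the ICER point, and the acceptance threshold line of slope `k_line`.
#' Draws strictly below the line (`delta_tc < k_line * delta_e`) lie in the
#' sustainability area; a draw exactly on the line does not count.
#'
#' @param inc A [increments()] tibble.
#' @param k_line Willingness-to-pay slope of the reference line (default
#'   25,000 currency units per QALY).
#' @return A list of class `cea_cep`: `samples` (tibble `draw`, `delta_e`,
#'   `delta_tc`, `quadrant`, `below_line`), `icer`, `k_line`,
#'   `quadrant_shares`, `prob_sustainable`.
#' @export
cep_table <- function(inc, k_line = 25000) {
  if (nrow(inc) == 0L) stop("no draws", call. = FALSE)
  quadrant <- dplyr::case_when(
    inc$delta_e >= 0 & inc$delta_tc >= 0 ~ "NE",
    inc$delta_e >= 0 & inc$delta_tc < 0 ~ "SE",
    inc$delta_e < 0 & inc$delta_tc >= 0 ~ "NW",
    TRUE ~ "SW")
  samples <- tibble::tibble(draw = inc$draw, delta_e = inc$delta_e,
                            delta_tc = inc$delta_tc, quadrant = quadrant,
                            below_line = inc$delta_tc < k_line * inc$delta_e)
  shares <- table(factor(quadrant, levels = c("NE", "SE", "SW", "NW")))
  structure(list(samples = samples,
                 icer = tryCatch(icer(inc), error = function(e) NA_real_),
                 k_line = k_line,
                 quadrant_shares = as.vector(shares) / nrow(inc),
                 prob_sustainable = mean(samples$below_line)),
            class = "cea_cep")
}

#' @export
print.cea_cep <- function(x, ...) {
  cat(sprintf("<cea_cep> %d draws, ICER %.0f, P(below k=%.0f line) = %.3f\n",
              nrow(x$samples), x$icer, x$k_line, x$prob_sustainable))
  invisible(x)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A [ceac()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cea_ceac
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$probability)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay k (currency per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness plane
#'
#' @param object A [cep_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cea_cep
#' @export
autoplot.cea_cep <- function(object, ...) {
  s <- object$samples
  ggplot2::ggplot(s, ggplot2::aes(x = .data$delta_e, y = .data$delta_tc)) +
    ggplot2::geom_point(alpha = 0.25, colour = "#2166ac", size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = object$k_line, intercept = 0,
                         linetype = "dashed") +
    ggplot2::annotate("point", x = mean(s$delta_e), y = mean(s$delta_tc),
                      colour = "#b2182b", size = 2.5) +
    ggplot2::labs(x = expression(Delta * e ~ "(QALYs)"),
                  y = expression(Delta * tc ~ "(currency)"),
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
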