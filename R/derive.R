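#' Quality-adjusted life-years by the trapezoid rule
#'
#' `e = sum_j (u_j + u_{j-1}) * delta_j / 2` over the follow-up intervals,
#' where `delta_j` is the fraction of the time unit between visit `j-1` and
#' `j`. The QALY is missing whenever any utility in the sequence is
#' missing; no part of the trajectory is interpolated or assumed.
#'
#' @param u Numeric utility sequence `u_0..u_J` (length `J + 1`).
#' @param schedule A [schedule()] with `J` follow-ups, or a numeric vector
#'   of the `J` interval fractions `delta`.
#' @return A single QALY value, or `NA` if any utility is missing.
#' @examples
#' qaly(c(0.4, 0.6, 0.8), c(0.5, 0.5)) # 0.6
#' @export
qaly <- function(u, schedule = trialcea::schedule()) {
  delta <- if (inherits(schedule, "visit_schedule")) {
    schedule_delta(schedule)
  } else {
    as.numeric(schedule)
  }
  if (length(u) != length(delta) + 1L) {
    stop("utility sequence must have one more entry than the schedule has ",
         "intervals", call. = FALSE)
  }
  if (anyNA(u)) return(NA_real_)
  sum((u[-1] + u[-length(u)]) * delta / 2)
}

# row-wise trapezoid over an n x (J+1) utility matrix; NA-propagating
qaly_matrix <- function(u, delta) {
  J <- length(delta)
  acc <- rep(0, nrow(u))
  for (j in seq_len(J)) {
    acc <- acc + (u[, j + 1] + u[, j]) * delta[j] / 2
  }
  acc
}

#' Per-time and total costs with strict missingness propagation
#'
#' Service-level costs are `unit_price * HRU`; the per-time cost is the sum
#' across services and the total cost the sum across follow-up visits
#' (baseline costs are computed but excluded from the total, which covers
#' the follow-up period only). Missingness propagates strictly: a per-time
#' cost is missing as soon as any service item is missing at that visit,
#' and the total is missing as soon as any follow-up per-time cost is.
#'
#' @param data A [trial_data()] object.
#' @return A tibble with columns `id`, `arm`, `time`, `cost` (one row per
#'   individual and visit) — per-service costs available via
#'   `per_service = TRUE` as additional `cost_<service>` columns.
#' @param per_service If `TRUE`, include per-service cost columns.
#' @export
cost_outcomes <- function(data, per_service = FALSE) {
  cat <- catalog_of(data)
  df <- tibble::as_tibble(data)
  hru <- as.matrix(df[cat$service])
  costs <- sweep(hru, 2, cat$unit_price, `*`)
  out <- tibble::tibble(id = df$id, arm = df$arm, time = df$time,
                        cost = rowSums(costs))
  if (per_service) {
    cs <- tibble::as_tibble(as.data.frame(costs))
    names(cs) <- paste0("cost_", cat$service)
    out <- dplyr::bind_cols(out, cs)
  }
  out
}

#' Per-individual derived outcomes: QALYs and total costs
#'
#' One row per individual with baseline utility, the QALY, per-time costs
#' and the follow-up total cost, all with strict missingness propagation
#' (see [cost_outcomes()] and [qaly()]).
#'
#' @param data A [trial_data()] object.
#' @return A tibble with columns `id`, `arm`, `u_0..u_J`, `cost_0..cost_J`,
#'   `qaly`, `total_cost`.
#' @export
derive_outcomes <- function(data) {
  sched <- schedule_of(data)
  delta <- schedule_delta(sched)
  times <- sched$time
  df <- tibble::as_tibble(data)

  u_wide <- tidyr::pivot_wider(df[c("id", "arm", "time", "utility")],
                               names_from = "time", values_from = "utility",
                               names_prefix = "u_")
  cost_wide <- tidyr::pivot_wider(cost_outcomes(data),
                                  names_from = "time", values_from = "cost",
                                  names_prefix = "cost_")
  out <- dplyr::left_join(u_wide, cost_wide, by = c("id", "arm"))
  umat <- as.matrix(out[paste0("u_", times)])
  cmat <- as.matrix(out[paste0("cost_", times[-1])])
  out$qaly <- ifelse(rowSums(is.na(umat)) > 0, NA_real_,
                     qaly_matrix(umat, delta))
  out$total_cost <- rowSums(cmat)  # NA as soon as any follow-up cost is NA
  out
}

#' Preprocessing strategies for partially observed resource use
#'
#' The three ways of confronting nonresponse before model fitting:
#' \describe{
#'   \item{`"ALL"`}{no imputation — the data are untouched and missingness
#'     propagates into costs and totals, to be handled inside the Bayesian
#'     model.}
#'   \item{`"IMP-H"`}{item nonresponse imputed as zero: at any visit where
#'     at least one service is observed, every missing service item is set
#'     to 0 (no use assumed) before costing. Visits where the whole
#'     resource-use questionnaire is missing (unit nonresponse) are left
#'     missing, so per-time and total costs can still be missing.
#'     Utilities are never touched.}
#'   \item{`"IMP-HC"`}{as `"IMP-H"`, and then any still-missing per-time
#'     cost is also set to 0 before totals are formed, yielding fully
#'     observed costs.}
#' }
#' Zero imputation fabricates data — it systematically drags cost estimates
#' down when true unobserved use is positive — and is provided here as the
#' comparator the modelling layer is designed to make unnecessary.
#'
#' @param data A [trial_data()] object.
#' @param strategy `"ALL"`, `"IMP-H"` or `"IMP-HC"`.
#' @return A list with `data` (the possibly modified [trial_data()]) and
#'   `outcomes` ([derive_outcomes()] of it, with `"IMP-HC"`'s cost-level
#'   zeroing applied).
#' @export
apply_strategy <- function(data, strategy = c("ALL", "IMP-H", "IMP-HC")) {
  strategy <- match.arg(strategy)
  cat <- catalog_of(data)
  if (strategy == "ALL") {
    return(list(data = data, outcomes = derive_outcomes(data),
                strategy = strategy))
  }
  df <- tibble::as_tibble(data)
  hru <- as.matrix(df[cat$service])
  item_rows <- rowSums(!is.na(hru)) > 0  # >=1 item observed: item nonresponse
  hru[item_rows, ][is.na(hru[item_rows, ])] <- 0
  df[cat$service] <- as.data.frame(hru)
  imputed <- rebuild_trial_data(df, data)
  outcomes <- derive_outcomes(imputed)
  if (strategy == "IMP-HC") {
    sched <- schedule_of(data)
    cost_cols <- paste0("cost_", sched$time)
    for (cc in cost_cols) {
      outcomes[[cc]][is.na(outcomes[[cc]])] <- 0
    }
    cmat <- as.matrix(outcomes[paste0("cost_", sched$time[-1])])
    outcomes$total_cost <- rowSums(cmat)
  }
  list(data = imputed, outcomes = outcomes, strategy = strategy)
}
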