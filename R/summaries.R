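#' Missingness summary by outcome and time
#'
#' Tabulates, for each outcome (utility and each service) and time point,
#' the number and proportion of individuals with a missing value, in the
#' layout conventional for trial missing-data reports: marginal rows/columns
#' labelled `"any"` give, per outcome, the count of individuals missing that
#' outcome at *any* time; per time, the count of individuals missing *any*
#' outcome at that time (incomplete cases at that time); and the
#' `("any", "any")` cell, the overall number of incomplete cases.
#'
#' @param data A [trial_data()] object.
#' @return A tibble of class `missingness_summary` with columns `outcome`,
#'   `time` (`"0"..J` and `"any"`), `n_missing`, `prop_missing`; the number
#'   of individuals is carried in attribute `n`.
#' @export
summarize_missingness <- function(data) {
  cat <- catalog_of(data)
  outcomes <- c("utility", cat$service)
  times <- schedule_of(data)$time
  ids <- unique(data$id)
  n <- length(ids)

  miss_long <- tidyr::pivot_longer(
    tibble::as_tibble(data)[c("id", "time", outcomes)],
    cols = dplyr::all_of(outcomes),
    names_to = "outcome", values_to = "value"
  )
  miss_long$missing <- is.na(miss_long$value)

  per_cell <- dplyr::summarise(
    dplyr::group_by(miss_long, .data$outcome, .data$time),
    n_missing = sum(.data$missing), .groups = "drop"
  )
  per_cell$time <- as.character(per_cell$time)

  per_outcome <- dplyr::summarise(
    dplyr::group_by(miss_long, .data$outcome),
    n_missing = dplyr::n_distinct(.data$id[.data$missing]), .groups = "drop"
  )
  per_outcome$time <- "any"

  per_time <- dplyr::summarise(
    dplyr::group_by(miss_long, .data$time),
    n_missing = dplyr::n_distinct(.data$id[.data$missing]), .groups = "drop"
  )
  per_time$outcome <- "any"
  per_time$time <- as.character(per_time$time)

  overall <- tibble::tibble(
    outcome = "any", time = "any",
    n_missing = dplyr::n_distinct(miss_long$id[miss_long$missing])
  )

  out <- dplyr::bind_rows(per_cell, per_outcome, per_time, overall)
  out$prop_missing <- out$n_missing / n
  out <- out[order(match(out$outcome, c(outcomes, "any")),
                   match(out$time, c(as.character(times), "any"))), ]
  structure(tibble::as_tibble(out), n = n,
            class = c("missingness_summary", class(tibble::tibble())))
}

#' Structural zeros per service
#'
#' An individual is a structural zero for service `k` if the service is
#' observed at *all* time points and every reported value is 0; anyone with
#' a missing value for that service is excluded (their profile may yet hide
#' use), as is anyone with any positive report. These individuals are
#' modelled by the point-mass component of the hurdle model.
#'
#' @param data A [trial_data()] object.
#' @param service Optional character vector restricting the services
#'   summarised; default all catalogued services.
#' @return A tibble with columns `service`, `n_structural_zero`,
#'   `prop_structural_zero` (denominator: all `n` individuals).
#' @export
structural_zeros <- function(data, service = NULL) {
  cat <- catalog_of(data)
  if (is.null(service)) service <- cat$service
  stopifnot(all(service %in% cat$service))
  n <- dplyr::n_distinct(data$id)
  res <- purrr::map_dfr(service, function(s) {
    per_id <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(data), .data$id),
      sz = all(!is.na(.data[[s]])) && all(.data[[s]] == 0),
      .groups = "drop"
    )
    tibble::tibble(service = s, n_structural_zero = sum(per_id$sz))
  })
  res$prop_structural_zero <- res$n_structural_zero / n
  res
}
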