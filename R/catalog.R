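#' Service catalog: the priced health care services of a trial
#'
#' A service catalog lists the `K` health care services whose use is recorded
#' in the resource-use questionnaire, together with a national unit price
#' per contact for each. Per-time, per-service costs are obtained as
#' `cost = unit_price * HRU`.
#'
#' @param service Character vector of unique service identifiers, in the
#'   column order used by the trial data (e.g. `"GP"`, `"NURSE"`).
#' @param unit_price Non-negative numeric vector of unit prices, one per
#'   service, in currency units per contact.
#'
#' @return A tibble of class `service_catalog` with columns `service` and
#'   `unit_price`.
#' @examples
#' service_catalog(c("GP", "NURSE"), c(40, 45))
#' @export
service_catalog <- function(service, unit_price) {
  if (length(service) < 1L) {
    stop("a service catalog needs at least one service", call. = FALSE)
  }
  if (anyDuplicated(service)) {
    stop("service identifiers must be unique", call. = FALSE)
  }
  if (length(unit_price) != length(service)) {
    stop("`unit_price` must have one entry per service", call. = FALSE)
  }
  if (any(!is.finite(unit_price)) || any(unit_price < 0)) {
    stop("unit prices must be finite and non-negative", call. = FALSE)
  }
  out <- tibble::tibble(service = as.character(service),
                        unit_price = as.numeric(unit_price))
  class(out) <- c("service_catalog", class(out))
  out
}

#' Default service catalog for the reference study design
#'
#' Nine community mental-health services: psychiatric doctor (PSYDR),
#' psychologist (PSYCH), physiotherapist (PHYSI), dentist (DENT), social
#' worker (SOCWORK), community worker (COMWORK), general practitioner (GP),
#' nurse (NURSE) and private therapist (THERAP). The unit prices are
#' synthetic defaults in the range of published UK unit-cost compendia; the
#' reference study does not publish its price vector, so these values stand
#' in for analyses of simulated data and should be replaced with the actual
#' national prices for a real evaluation.
#'
#' @return A [service_catalog()] with `K = 9` services.
#' @export
default_service_catalog <- function() {
  service_catalog(
    service    = c("PSYDR", "PSYCH", "PHYSI", "DENT", "SOCWORK",
                   "COMWORK", "GP", "NURSE", "THERAP"),
    unit_price = c(150, 100, 60, 80, 55, 40, 40, 45, 50)
  )
}

#' Follow-up schedule of a trial
#'
#' Outcomes are collected at baseline (`time = 0`) and `J` follow-ups
#' (`time = 1..J`). `delta[j]` is the fraction of the time unit (typically
#' one year) covered between time `j - 1` and time `j`; it weights both the
#' trapezoid QALY computation and nothing else. For the common
#' baseline / 6 months / 12 months design on a one-year unit,
#' `delta = c(0.5, 0.5)`.
#'
#' @param delta Positive numeric vector of length `J` of interval fractions.
#' @return A tibble of class `visit_schedule` with columns `time` (`0..J`)
#'   and `delta` (`NA` at baseline).
#' @examples
#' schedule()            # baseline + 6m + 12m on a 1-year unit
#' schedule(c(0.25, 0.25, 0.5))
#' @export
schedule <- function(delta = c(0.5, 0.5)) {
  if (length(delta) < 1L || any(!is.finite(delta)) || any(delta <= 0)) {
    stop("`delta` must be a non-empty vector of positive fractions",
         call. = FALSE)
  }
  if (sum(delta) > 1 + 1e-8) {
    warning("schedule spans more than one time unit (sum(delta) > 1)",
            call. = FALSE)
  }
  out <- tibble::tibble(time = 0:length(delta),
                        delta = c(NA_real_, as.numeric(delta)))
  class(out) <- c("visit_schedule", class(out))
  out
}

n_followups <- function(sched) nrow(sched) - 1L

schedule_delta <- function(sched) sched$delta[-1L]
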