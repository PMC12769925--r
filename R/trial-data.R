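#' Assemble and validate a long-format trial dataset
#'
#' The canonical container is a long tibble with one row per individual and
#' time point: columns `id`, `arm` (0 = control, 1 = intervention), `time`
#' (`0..J`), `utility` (preference-based HRQoL score, at most 1) and one
#' column per catalogued service holding the reported number of contacts.
#' Missing values are encoded explicitly as `NA`: a literal 0 always means a
#' *reported* zero. This distinction is the crux of the whole analysis —
#' silently recoding nonresponse as zero use is exactly the practice the
#' modelling layer is designed to replace.
#'
#' @param df Data frame in long format (see Details).
#' @param schedule A [schedule()].
#' @param catalog A [service_catalog()]; its services must match the service
#'   columns of `df`.
#' @return A tibble of class `trial_data` carrying the schedule and catalog
#'   as attributes (retrieve with [schedule_of()] / [catalog_of()]).
#' @export
trial_data <- function(df, schedule = trialcea::schedule(),
                       catalog = default_service_catalog()) {
  df <- tibble::as_tibble(df)
  required <- c("id", "arm", "time", "utility")
  miss_col <- setdiff(required, names(df))
  if (length(miss_col)) {
    stop("missing required column(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  }
  # one numeric type throughout so a written-then-read dataset is identical
  for (cc in intersect(names(df), c(required, catalog$service))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  extra <- setdiff(names(df), c(required, catalog$service))
  if (length(extra)) {
    stop("unknown service column(s) not in catalog: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(catalog$service, names(df))
  if (length(absent)) {
    stop("catalog service(s) absent from data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  bad_arm <- which(!df$arm %in% c(0, 1))
  if (length(bad_arm)) {
    stop("`arm` must be 0 or 1 (first offending row: ", bad_arm[1], ")",
         call. = FALSE)
  }
  dup <- which(duplicated(df[c("id", "time")]))
  if (length(dup)) {
    stop("duplicate (id, time) row: ", dup[1], call. = FALSE)
  }
  times <- schedule$time
  bad_t <- which(!df$time %in% times)
  if (length(bad_t)) {
    stop("`time` outside the schedule (row ", bad_t[1], ")", call. = FALSE)
  }
  # every individual must carry a single arm label
  arm_n <- dplyr::summarise(dplyr::group_by(df, .data$id),
                            k = dplyr::n_distinct(.data$arm))
  if (any(arm_n$k != 1L)) {
    stop("individual(s) with inconsistent arm labels: ",
         paste(utils::head(arm_n$id[arm_n$k != 1L], 3), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(df$arm)) < 2L) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  hru <- as.matrix(df[catalog$service])
  if (any(hru < 0, na.rm = TRUE)) {
    stop("observed HRU values must be non-negative", call. = FALSE)
  }
  if (any(df$utility > 1 + 1e-9, na.rm = TRUE)) {
    stop("observed utilities must not exceed 1", call. = FALSE)
  }
  # complete the panel: every id appears at every scheduled time
  df <- df[order(df$id, df$time), ]
  df <- tidyr::complete(df, .data$id, time = times)
  df <- dplyr::group_by(df, .data$id)
  df <- dplyr::mutate(df, arm = .data$arm[!is.na(.data$arm)][1])
  df <- dplyr::ungroup(df)
  structure(df,
            schedule = schedule, catalog = catalog,
            class = c("trial_data", class(tibble::tibble())))
}

#' @rdname trial_data
#' @param data A `trial_data` object.
#' @export
schedule_of <- function(data) attr(data, "schedule", exact = TRUE)

#' @rdname trial_data
#' @export
catalog_of <- function(data) attr(data, "catalog", exact = TRUE)

#' Read / write a long-format trial CSV
#'
#' The on-disk interchange format is a plain CSV with columns `id`, `arm`,
#' `time`, `utility` and one column per service; empty cells denote missing
#' values. `write_trial_csv()` followed by `read_trial_csv()` round-trips
#' every observed value and every missing flag.
#'
#' @param path File path.
#' @inheritParams trial_data
#' @return `read_trial_csv()` returns a validated [trial_data()] object;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
read_trial_csv <- function(path, schedule = trialcea::schedule(),
                           catalog = default_service_catalog()) {
  # parse as text, convert with strtod: exact round-trip of written doubles
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"), progress = FALSE)
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), as.numeric))
  trial_data(df, schedule = schedule, catalog = catalog)
}

#' @rdname read_trial_csv
#' @param data A `trial_data` object.
#' @export
write_trial_csv <- function(data, path) {
  df <- tibble::as_tibble(data)
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }))
  readr::write_csv(df, path, na = "")
  invisible(path)
}

as_trial_tibble <- function(data) {
  out <- data
  class(out) <- class(tibble::tibble())
  attr(out, "schedule") <- NULL
  attr(out, "catalog") <- NULL
  out
}

rebuild_trial_data <- function(df, template) {
  structure(tibble::as_tibble(df),
            schedule = schedule_of(template), catalog = catalog_of(template),
            class = class(template))
}
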