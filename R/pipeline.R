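# End-to-end orchestration: simulate/read -> derive -> fit -> evaluate.

# the strategy x missingness grid that is statistically meaningful:
# zero-imputation approaches exist only where the model is fitted above the
# level at which the imputation happens.
allowed_combos <- function() {
  tibble::tibble(
    strategy = c("s1", "s1", "s1", "s2", "s2", "s3"),
    missingness = c("ALL", "IMP-H", "IMP-HC", "ALL", "IMP-H", "ALL")
  )
}

#' Configure an end-to-end run
#'
#' @param input A [sim_config()] to simulate from, or a path to a
#'   long-format trial CSV (read with `schedule`/`catalog`).
#' @param combos Tibble with columns `strategy` (`"s1"|"s2"|"s3"`) and
#'   `missingness` (`"ALL"|"IMP-H"|"IMP-HC"`); defaults to the full allowed
#'   grid. Combinations outside S1:{ALL, IMP-H, IMP-HC}, S2:{ALL, IMP-H},
#'   S3:{ALL} are rejected.
#' @param schedule,catalog Used when `input` is a CSV path.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param k_grid Willingness-to-pay grid for the CEAC.
#' @param k_line Reference threshold slope for the CEP.
#' @param out_dir Output directory (created); `NULL` for no file output.
#' @param seed Master seed: drives simulation and all chains.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = default_study_config(),
                       combos = allowed_combos(),
                       schedule = trialcea::schedule(),
                       catalog = default_service_catalog(),
                       priors = prior_spec(),
                       mcmc = mcmc_config(),
                       k_grid = seq(0, 10000, by = 100),
                       k_line = 25000,
                       out_dir = NULL,
                       seed = 1L) {
  combos <- tibble::as_tibble(combos)
  ok <- allowed_combos()
  bad <- dplyr::anti_join(combos, ok, by = c("strategy", "missingness"))
  if (nrow(bad)) {
    stop("invalid strategy/missingness combination(s): ",
         paste(paste0(toupper(bad$strategy), "+", bad$missingness),
               collapse = ", "),
         "; allowed: S1:{ALL, IMP-H, IMP-HC}, S2:{ALL, IMP-H}, S3:{ALL}",
         call. = FALSE)
  }
  structure(list(input = input, combos = combos, schedule = schedule,
                 catalog = catalog, priors = priors, mcmc = mcmc,
                 k_grid = k_grid, k_line = k_line, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

fit_combo <- function(data, strategy, missingness, priors, mcmc) {
  prep <- apply_strategy(data, missingness)
  switch(strategy,
    s1 = fit_s1(prep$outcomes, priors = priors, mcmc = mcmc),
    s2 = fit_s2(data, outcomes = prep$outcomes, priors = priors, mcmc = mcmc),
    s3 = fit_s3(data, priors = priors, mcmc = mcmc))
}

#' Run the whole analysis pipeline
#'
#' Simulates (or reads) the trial data, then for every requested strategy
#' and missingness approach derives outcomes, fits the Bayesian model,
#' computes convergence diagnostics and the cost-effectiveness layer, and
#' (when `out_dir` is set) writes the dataset, per-combination posterior
#' summaries, CEAC/CEP tables, a comparison table of posterior means and
#' 95% equal-tailed credible intervals of `mu_tc` and `mu_e` per arm
#' (costs rounded to whole currency units, QALYs to 3 decimals), and a
#' metadata file with the config hash, seed and package version so that
#' reruns are reproducible.
#'
#' @param config A [run_config()].
#' @return A list: `data`, `truth` (when simulated), `fits`,
#'   `diagnostics`, `ce` (per combination: increments, icer, ceac, cep),
#'   `comparison` (the rounded comparison tibble), `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  wpath <- function(...) file.path(out_dir, ...)

  truth <- NULL
  if (inherits(config$input, "sim_config")) {
    sim <- simulate_trial(config$input)
    data <- sim$data
    truth <- sim$truth
    if (!is.null(out_dir)) {
      write_trial_csv(data, wpath("dataset.csv"))
      jsonlite::write_json(list(mu_e = as.list(truth$mu_e),
                                mu_tc = as.list(truth$mu_tc),
                                pi_k = as.list(truth$pi_k)),
                           wpath("ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  } else {
    data <- read_trial_csv(config$input, schedule = config$schedule,
                           catalog = config$catalog)
  }

  combos <- config$combos
  mcmc <- config$mcmc
  mcmc$seed <- config$seed
  results <- purrr::pmap(combos, function(strategy, missingness) {
    fit <- fit_combo(data, strategy, missingness, config$priors, mcmc)
    diag <- diagnose(fit)
    inc <- increments(fit)
    list(fit = fit, diagnostics = diag, increments = inc,
         icer = tryCatch(icer(inc), error = function(e) NA_real_),
         ceac = ceac(inc, config$k_grid),
         cep = cep_table(inc, config$k_line))
  })
  names(results) <- paste0(toupper(combos$strategy), "_", combos$missingness)

  comparison <- purrr::map2_dfr(results, names(results), function(res, nm) {
    td <- tidy(res$fit)
    td <- td[td$term %in% c("mu_e", "mu_tc"), ]
    td$combo <- nm
    td
  })
  rnd <- function(v, term) ifelse(term == "mu_tc", round(v), round(v, 3))
  comparison <- dplyr::mutate(comparison,
    estimate = rnd(.data$estimate, .data$term),
    conf.low = rnd(.data$conf.low, .data$term),
    conf.high = rnd(.data$conf.high, .data$term))
  comparison <- comparison[c("combo", "term", "arm", "estimate",
                             "conf.low", "conf.high")]

  if (!is.null(out_dir)) {
    readr::write_csv(comparison, wpath("comparison.csv"))
    for (nm in names(results)) {
      res <- results[[nm]]
      readr::write_csv(tidy(res$fit), wpath(paste0("summary_", nm, ".csv")))
      readr::write_csv(res$ceac, wpath(paste0("ceac_", nm, ".csv")))
      readr::write_csv(res$cep$samples, wpath(paste0("cep_", nm, ".csv")))
      jsonlite::write_json(
        list(icer = res$icer,
             prob_sustainable = res$cep$prob_sustainable,
             max_rhat = max(res$diagnostics$rhat, na.rm = TRUE),
             min_ess = min(res$diagnostics$ess, na.rm = TRUE),
             converged = attr(res$diagnostics, "converged")),
        wpath(paste0("evaluation_", nm, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    meta <- list(
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("trialcea")),
      increment_orientation = "intervention minus control",
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(meta, wpath("metadata.json"), auto_unbox = TRUE)
  }

  list(data = data, truth = truth,
       fits = purrr::map(results, "fit"),
       diagnostics = purrr::map(results, "diagnostics"),
       ce = purrr::map(results, function(r) r[c("increments", "icer",
                                                "ceac", "cep")]),
       comparison = comparison,
       paths = if (is.null(out_dir)) NULL else normalizePath(out_dir))
}
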