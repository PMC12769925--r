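test_that("catalog and schedule constructors validate their invariants", {
  expect_error(service_catalog(c("GP", "GP"), c(1, 2)), "unique")
  expect_error(service_catalog("GP", -1), "non-negative")
  expect_error(service_catalog(character(0), numeric(0)), "at least one")
  expect_error(schedule(c(0.5, -0.1)), "positive")
  expect_warning(schedule(c(0.7, 0.7)), "more than one time unit")
  s <- schedule(c(0.25, 0.25, 0.5))
  expect_equal(s$time, 0:3)
  expect_equal(s$delta, c(NA, 0.25, 0.25, 0.5))
})

test_that("trial_data validates structure and reports offending rows", {
  cat3 <- tiny_catalog()
  ok <- tibble::tibble(id = rep(1:2, each = 3), arm = rep(c(0, 1), each = 3),
                       time = rep(0:2, 2), utility = 0.5,
                       GP = 1, NURSE = 0, THERAP = 0)
  expect_s3_class(trial_data(ok, catalog = cat3), "trial_data")

  bad_arm <- ok; bad_arm$arm[4] <- 2
  expect_error(trial_data(bad_arm, catalog = cat3), "arm")
  dup <- ok; dup$time[2] <- 0
  expect_error(trial_data(dup, catalog = cat3), "duplicate")
  unk <- ok; unk$DENTIST <- 1
  expect_error(trial_data(unk, catalog = cat3), "unknown service")
  neg <- ok; neg$GP[1] <- -1
  expect_error(trial_data(neg, catalog = cat3), "non-negative")
  high_u <- ok; high_u$utility[1] <- 1.2
  expect_error(trial_data(high_u, catalog = cat3), "exceed 1")
})

test_that("a toy CSV parses with empty cells flagged missing, never zero", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,arm,time,utility,GP,NURSE,THERAP",
    "1,0,0,0.5,2,0,1",
    "1,0,1,,0,1,0",
    "1,0,2,0.7,1,0,0",
    "2,1,0,0.4,0,,0",
    "2,1,1,0.6,3,2,0",
    "2,1,2,0.8,0,0,0"), tmp)
  d <- read_trial_csv(tmp, schedule(c(0.5, 0.5)), tiny_catalog())
  expect_equal(length(unique(d$id)), 2)
  expect_true(is.na(d$utility[d$id == 1 & d$time == 1]))
  expect_true(is.na(d$NURSE[d$id == 2 & d$time == 0]))
  # observed zeros stay zeros
  expect_identical(d$GP[d$id == 1 & d$time == 1], 0)
  expect_identical(d$NURSE[d$id == 1 & d$time == 0], 0)
})

test_that("write-then-read round-trips a simulated dataset identically", {
  sim <- simulate_trial(small_config(seed = 3))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(sim$data, tmp)
  back <- read_trial_csv(tmp, schedule_of(sim$data), catalog_of(sim$data))
  expect_identical(as.data.frame(sim$data), as.data.frame(back))
})

test_that("missingness summary counts match the hand-built panel", {
  ms <- summarize_missingness(tiny_data())
  get <- function(o, t) ms$n_missing[ms$outcome == o & ms$time == t]
  expect_equal(get("utility", "0"), 1)  # individual 4
  expect_equal(get("utility", "1"), 1)  # individual 2
  expect_equal(get("GP", "1"), 2)       # individuals 1 and 2
  expect_equal(get("GP", "any"), 2)
  expect_equal(get("any", "1"), 2)      # incomplete cases at time 1
  expect_equal(get("any", "any"), 3)    # individuals 1, 2, 4
  expect_equal(ms$prop_missing[ms$outcome == "GP" & ms$time == "1"], 0.5)
})

test_that("missingness proportions are counts over n (2 of 10 -> 20%)", {
  df <- tidyr::expand_grid(id = 1:10, time = 0:2)
  df$arm <- ifelse(df$id <= 5, 0, 1)
  df$utility <- 0.5
  df$GP <- 1; df$NURSE <- 0; df$THERAP <- 0
  df$GP[df$time == 1 & df$id %in% c(3, 7)] <- NA
  ms <- summarize_missingness(trial_data(df, catalog = tiny_catalog()))
  expect_equal(ms$n_missing[ms$outcome == "GP" & ms$time == "1"], 2)
  expect_equal(ms$prop_missing[ms$outcome == "GP" & ms$time == "1"], 0.2)
})

test_that("fully observed data yield an all-zero missingness summary", {
  sim <- simulate_trial(small_config(seed = 4, miss = FALSE))
  ms <- summarize_missingness(sim$data)
  expect_true(all(ms$n_missing == 0))
  expect_true(all(ms$prop_missing == 0))
})

test_that("overall incomplete count equals the brute-force union of missing sets", {
  for (seed in 1:5) {
    sim <- simulate_trial(small_config(seed = seed))
    d <- tibble::as_tibble(sim$data)
    outcome_cols <- c("utility", catalog_of(sim$data)$service)
    union_ids <- unique(d$id[rowSums(is.na(d[outcome_cols])) > 0])
    ms <- summarize_missingness(sim$data)
    expect_equal(ms$n_missing[ms$outcome == "any" & ms$time == "any"],
                 length(union_ids))
  }
})

test_that("structural zeros: complete all-zero profiles only, order-invariant", {
  d <- tiny_data()
  sz <- structural_zeros(d)
  # GP: id2 has NA at time 1 (excluded), id4 all-zero observed -> 1
  expect_equal(sz$n_structural_zero[sz$service == "GP"], 1)
  # NURSE: id2 excluded (NA), id4 qualifies -> 1
  expect_equal(sz$n_structural_zero[sz$service == "NURSE"], 1)
  # THERAP: id1 all zero complete, id2 NA-excluded, id4 qualifies -> 2
  expect_equal(sz$n_structural_zero[sz$service == "THERAP"], 2)
  expect_equal(sz$prop_structural_zero, sz$n_structural_zero / 4)

  # shuffling rows and perturbing other services changes nothing
  df <- tibble::as_tibble(d)
  set.seed(1)
  df <- df[sample(nrow(df)), ]
  df$GP <- df$GP + 5
  d2 <- trial_data(df, schedule_of(d), catalog_of(d))
  expect_equal(structural_zeros(d2, "THERAP")$n_structural_zero, 2)
  expect_equal(structural_zeros(d2, "NURSE")$n_structural_zero, 1)
})
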