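test_that("increments are oriented intervention minus control and antisymmetric", {
  df <- tibble::tibble(arm = c(0, 0, 1, 1),
                       mu_e = c(0.5, 0.5, 0.6, 0.6),
                       mu_tc = c(2600, 2600, 2500, 2500))
  inc <- increments(df)
  expect_equal(inc$delta_e, c(0.1, 0.1))
  expect_equal(inc$delta_tc, c(-100, -100))

  # identical arms: all increments zero
  same <- df; same$mu_e <- 0.5; same$mu_tc <- 2600
  inc0 <- increments(same)
  expect_true(all(inc0$delta_e == 0) && all(inc0$delta_tc == 0))

  # swapping arm labels negates both increments
  swapped <- df; swapped$arm <- 1 - swapped$arm
  inc_sw <- increments(swapped)
  expect_equal(inc_sw$delta_e, -inc$delta_e)
  expect_equal(inc_sw$delta_tc, -inc$delta_tc)

  expect_error(increments(df[1:3, ]), "equal")
})

test_that("the ICER is the ratio of mean increments", {
  inc <- increments(tibble::tibble(arm = c(0, 1), mu_e = c(0.5, 0.6),
                                   mu_tc = c(2600, 2500)))
  expect_equal(icer(inc), -1000)
  inc2 <- inc; inc2$delta_tc <- inc2$delta_tc * 2
  expect_equal(icer(inc2), 2 * icer(inc))
  inc3 <- inc; inc3$delta_tc <- 0
  expect_equal(icer(inc3), 0)
  inc4 <- inc; inc4$delta_e <- 0
  expect_error(icer(inc4), "undefined")
})

test_that("the CEAC counts strictly positive net benefit", {
  inc <- structure(tibble::tibble(draw = 1:4,
                                  delta_e = c(0.1, 0.2, -0.05, 0.1),
                                  delta_tc = c(100, -50, -200, 2000)),
                   class = c("cea_increments", class(tibble::tibble())))
  # at k = 1000 net benefits are (0, 250, 150, -1900): one is exactly on
  # the line and does not count, two are strictly positive
  cv <- ceac(inc, k_grid = c(0, 1000))
  expect_equal(cv$probability[cv$k == 1000], 0.5)
  expect_equal(cv$probability[cv$k == 0], mean(inc$delta_tc < 0))
  expect_error(ceac(inc, numeric(0)), "non-empty")
  expect_error(ceac(inc, c(0, 0, 100)), "strictly increasing")
})

test_that("CEAC identities and brute-force agreement on random draws", {
  for (seed in 1:5) {
    inc <- increments(fake_arm_draws(400, seed = seed))
    grid <- c(0, 500, 2500, 10000, 1e9)
    cv <- ceac(inc, grid)
    expect_true(all(cv$probability >= 0 & cv$probability <= 1))
    expect_identical(cv$probability[cv$k == 0], mean(inc$delta_tc < 0))
    expect_identical(cv$probability[cv$k == 1e9], mean(inc$delta_e > 0))
    # brute force: re-evaluate each draw at each threshold
    brute <- vapply(grid, function(k) {
      mean(vapply(seq_len(nrow(inc)), function(i) {
        k * inc$delta_e[i] - inc$delta_tc[i] > 0
      }, logical(1)))
    }, numeric(1))
    expect_identical(cv$probability, brute)
  }
})

test_that("the cost-effectiveness plane partitions draws and matches the CEAC", {
  inc <- increments(fake_arm_draws(600, seed = 3))
  cep <- cep_table(inc, k_line = 2500)
  expect_equal(sum(table(cep$samples$quadrant)), nrow(inc))
  expect_equal(sum(cep$quadrant_shares), 1)
  expect_equal(cep$prob_sustainable,
               ceac(inc, k_grid = c(2500))$probability)
  # a draw exactly on the line is not below it
  on_line <- structure(tibble::tibble(draw = 1:2, delta_e = c(1, 1),
                                      delta_tc = c(2500, 2499)),
                       class = c("cea_increments", class(tibble::tibble())))
  cp <- cep_table(on_line, k_line = 2500)
  expect_equal(cp$samples$below_line, c(FALSE, TRUE))

  # dominant intervention: everything in the south-east quadrant
  dom <- structure(tibble::tibble(draw = 1:3, delta_e = c(0.1, 0.2, 0.3),
                                  delta_tc = c(-1, -2, -3)),
                   class = c("cea_increments", class(tibble::tibble())))
  expect_true(all(cep_table(dom)$samples$quadrant == "SE"))
  expect_equal(ceac(dom, c(0, 10))$probability, c(1, 1))
})

test_that("autoplot methods return ggplot objects", {
  inc <- increments(fake_arm_draws(100))
  expect_s3_class(ggplot2::autoplot(ceac(inc)), "ggplot")
  expect_s3_class(ggplot2::autoplot(cep_table(inc)), "ggplot")
})
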