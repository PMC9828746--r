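test_that("Williams NOED is the top dose when there is no signal", {
  set.seed(31)
  resp <- lapply(1:5, function(i) rnorm(3, 100, 2))
  ctrl <- rnorm(9, 100, 2)
  est <- williams_noed(1:5, resp, ctrl, direction = "decrease", nsim = 4000)
  expect_equal(est$value, 5)
  expect_equal(est$method, "williams")
})

test_that("Williams NOED lands below the first affected dose", {
  # strong monotone decline starting at dose 4; near-noiseless replicates
  set.seed(32)
  means <- c(100, 100, 100, 50, 30)
  resp <- lapply(means, function(m) rnorm(3, m, 1))
  ctrl <- rnorm(9, 100, 1)
  est <- williams_noed(1:5, resp, ctrl, direction = "decrease", nsim = 4000)
  expect_equal(est$value, 3)
  expect_equal(est$status, "ok")
})

test_that("Williams flags an effect below the lowest dose", {
  set.seed(33)
  resp <- lapply(c(50, 40, 30, 20, 10), function(m) rnorm(3, m, 1))
  ctrl <- rnorm(9, 100, 1)
  est <- williams_noed(1:5, resp, ctrl, direction = "decrease", nsim = 4000)
  expect_true(is.na(est$value))
  expect_equal(est$status, "all_doses_effect")
  expect_error(williams_noed(1:2, list(1, 2), c(1, 2)),
               "beescreen_williams_error")
})

test_that("trend statistic agrees with the base-R trend test", {
  set.seed(34)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    n <- rep(20, k)
    dead <- rbinom(k, 20, seq(0.1, 0.5, length.out = k))
    tt <- ca_trend_test(n, dead)
    ref <- suppressWarnings(prop.trend.test(dead, n))
    expect_equal(tt$z^2, unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("step-down trend NOED behaves on null, trending and reversed data", {
  null_d <- quantal_dose_response(1:4, rep(10, 4), rep(1, 4),
                                  control = list(n = 10, dead = 1))
  est0 <- stepdown_trend_noed(null_d)
  expect_equal(est0$value, 4)

  trend <- quantal_dose_response(1:3, rep(10, 3), c(1, 5, 10),
                                 control = list(n = 10, dead = 0))
  est1 <- stepdown_trend_noed(trend)
  expect_lt(est1$p_values[3], 0.05)    # full-set trend significant
  expect_true(is.na(est1$value) || est1$value < 3)

  rev_d <- quantal_dose_response(1:3, rep(10, 3), c(5, 2, 0),
                                 control = list(n = 10, dead = 10))
  est2 <- stepdown_trend_noed(rev_d)
  expect_equal(est2$value, 3)          # one-sided: no adverse trend
  expect_error(stepdown_trend_noed(
    quantal_dose_response(1, 10, 5, control = list(n = 10, dead = 0))),
    "beescreen_trend_error")
})

test_that("one-sided Fisher p matches hypergeometric enumeration", {
  # 9/1 dead/alive vs 1/9: P(X >= 9) = (C(10,9)C(10,1)+C(10,10)C(10,0))/C(20,10)
  p <- beescreen:::.fisher_one_sided(9, 10, 1, 10)
  expect_equal(p, 101 / 184756, tolerance = 1e-12)
  set.seed(35)
  for (i in 1:20) {
    n1 <- sample(5:15, 1); n0 <- sample(5:15, 1)
    d1 <- sample(0:n1, 1); d0 <- sample(0:n0, 1)
    ref <- fisher.test(matrix(c(d1, n1 - d1, d0, n0 - d0), nrow = 2),
                       alternative = "greater")$p.value
    expect_equal(beescreen:::.fisher_one_sided(d1, n1, d0, n0), ref,
                 tolerance = 1e-10)
  }
})

test_that("Fisher/Holm NOED on null and saturated data", {
  null_d <- quantal_dose_response(1:4, rep(10, 4), rep(1, 4),
                                  control = list(n = 10, dead = 1))
  est <- fisher_holm_noed(null_d)
  expect_true(all(est$p_adjusted == 1))
  expect_equal(est$value, 4)

  hot <- quantal_dose_response(1:3, rep(10, 3), c(10, 10, 10),
                               control = list(n = 10, dead = 0))
  esth <- fisher_holm_noed(hot)
  expect_true(is.na(esth$value))
  # identical significant groups: Holm multiplies the smallest by k
  expect_equal(esth$p_adjusted[1], min(3 * esth$p_raw[1], 1))
  expect_error(fisher_holm_noed(
    quantal_dose_response(1:2, c(10, 10), c(0, 0),
                          control = list(n = 0, dead = 0))),
    "beescreen_fisher_error")
})

test_that("Holm adjustment is monotone in the step-down order", {
  set.seed(36)
  for (i in 1:50) {
    k <- sample(3:8, 1)
    d <- quantal_dose_response(
      seq_len(k), rep(10, k), sample(0:10, k, replace = TRUE),
      control = list(n = 10, dead = sample(0:3, 1)))
    est <- fisher_holm_noed(d)
    ord <- order(est$p_raw)
    expect_true(all(diff(est$p_adjusted[ord]) >= -1e-12))
    expect_true(all(est$p_adjusted >= est$p_raw - 1e-12))
  }
})

test_that("test selection follows monotonicity and data type", {
  up <- quantal_dose_response(1:4, rep(10, 4), c(1, 3, 6, 9),
                              control = list(n = 10, dead = 0))
  expect_equal(decide_test(up), "cochran_armitage_stepdown")
  ushape <- quantal_dose_response(1:4, rep(10, 4), c(6, 2, 1, 8),
                                  control = list(n = 10, dead = 0))
  expect_equal(decide_test(ushape), "fisher_holm")
  cont <- list(dose = 1:4, response = lapply(1:4, function(i) rnorm(3)))
  expect_equal(decide_test(cont), "williams")
})

test_that("control comparison pools unless the solvent differs", {
  same <- compare_controls(list(n = 10, dead = 1), list(n = 10, dead = 1))
  expect_equal(same$choice, "pool_with_negative")
  diff_c <- compare_controls(list(n = 10, dead = 0), list(n = 10, dead = 8))
  expect_equal(diff_c$choice, "use_solvent")
  expect_true(diff_c$flagged)
  expect_equal(compare_controls(list(n = 10, dead = 0))$choice,
               "pool_with_negative")
  cont <- compare_controls(rnorm(5, 10, 0.1), rnorm(5, 10, 0.1) + 0.01)
  expect_true(cont$choice %in% c("pool_with_negative", "use_solvent"))
})
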