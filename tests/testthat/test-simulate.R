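test_that("one-sample log-rank statistic by hand", {
  m0 <- weibull_survival(shape = 1, scale = 1)
  # three patients: events at 0.5 and 0.25, one censored at 1.0
  r <- one_sample_logrank(c(0.5, 1.0, 0.25), c(1, 0, 1), m0)
  expect_equal(r$observed, 2)
  expect_equal(r$expected, 0.5 + 1.0 + 0.25)
  expect_equal(r$statistic, (2 - 1.75) / sqrt(1.75), tolerance = 1e-12)
  # O = E gives zero
  r0 <- one_sample_logrank(c(1, 1), c(1, 1), m0)
  expect_equal(r0$statistic, 0)
  # event-free with total exposure 4: Z = -2
  r2 <- one_sample_logrank(c(2, 2), c(0, 0), m0)
  expect_equal(r2$statistic, -2)
  # no exposure: statistic undefined
  expect_true(is.na(one_sample_logrank(c(0, 0), c(0, 0), m0)$statistic))
  # Weibull reference cumulative hazard
  mk <- weibull_survival(shape = 0.5, scale = 4)
  rk <- one_sample_logrank(c(1, 2.25), c(1, 0), mk)
  expect_equal(rk$expected, sqrt(1 / 4) + sqrt(2.25 / 4), tolerance = 1e-12)
})

test_that("simulation honours the futility boundary conventions", {
  hyp <- tab2_hyp()
  s <- simulate_oc(c(10, 20, -Inf, -1.64), hyp, accrual = 15,
                   under = "null", reps = 500, seed = 1)
  expect_equal(s$early_stop, 1)
  expect_equal(s$reject, 0)
  # same seed, same answer; different seed, (almost surely) different
  a <- simulate_oc(c(14, 30, 0.2, -1.64), hyp, 15, under = "alternative",
                   reps = 3000, seed = 7)
  b <- simulate_oc(c(14, 30, 0.2, -1.64), hyp, 15, under = "alternative",
                   reps = 3000, seed = 7)
  cdiff <- simulate_oc(c(14, 30, 0.2, -1.64), hyp, 15, under = "alternative",
                       reps = 3000, seed = 8)
  expect_identical(a$reject, b$reject)
  expect_false(a$reject == cdiff$reject)
})

test_that("null simulation tracks the asymptotic interim law", {
  hyp <- tab2_hyp()
  c1 <- 0.5
  s <- simulate_oc(c(20, 40, c1, -1.64), hyp, accrual = 15, under = "null",
                   reps = 20000, seed = 11)
  pet <- 1 - pnorm(c1)
  se <- sqrt(pet * (1 - pet) / s$reps)
  expect_lt(abs(s$early_stop - pet), 4 * se)
  # error control with slack for the asymptotic approximation
  expect_lt(s$reject, 0.05 + 3 * sqrt(0.05 * 0.95 / s$reps))
})

test_that("replicated estimates yield a containing interval", {
  hyp <- tab2_hyp()
  r <- replicate_interval(c(28, 52, -0.10, -1.64), hyp, 15,
                          under = "alternative", outer = 20, inner = 400,
                          seed = 5)
  expect_lte(r$interval[1], r$reject)
  expect_gte(r$interval[2], r$reject)
  r2 <- replicate_interval(c(28, 52, -0.10, -1.64), hyp, 15,
                           under = "alternative", outer = 20, inner = 400,
                           seed = 5)
  expect_identical(r$interval, r2$interval)
  d0 <- replicate_interval(c(10, 20, -Inf, -1.64), hyp, 15, under = "null",
                           outer = 5, inner = 100, seed = 2)
  expect_identical(unname(d0$interval), c(0, 0))
})

test_that("design argument validation", {
  hyp <- tab2_hyp()
  expect_error(simulate_oc(c(20, 20, 0, -1.6), hyp, 15), "n1 < n")
  expect_error(simulate_oc("nope", hyp, 15), "design")
})
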