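test_that("null operating characteristics follow the design formulas", {
  m <- design_metrics(44, 73, 0.240, accrual = 24, tc = 1)
  expect_equal(m$PET, 1 - pnorm(0.240), tolerance = 1e-12)
  expect_equal(m$ESS0, 44 + pnorm(0.240) * 29, tolerance = 1e-12)
  expect_equal(round(m$ESS0, 1), 61.3)
  expect_equal(m$ETSL0, 44 / 24 + pnorm(0.240) * (29 / 24 + 1),
               tolerance = 1e-12)
  expect_equal(round(m$ETSL0, 1), 3.1)
  m2 <- design_metrics(41, 79, -0.085, accrual = 24, tc = 1)
  expect_equal(round(m2$ESS0, 1), 58.7)
  expect_equal(round(m2$ETSL0, 1), 2.9)
  # futility-certain interim
  m3 <- design_metrics(10, 30, -Inf, accrual = 10, tc = 1)
  expect_equal(m3$PET, 1)
  expect_equal(m3$ESS0, 10)
  expect_equal(m3$ETSL0, 1)
})

test_that("single-n scan matches the published pancreatic design at the calibrated level", {
  hyp <- panc_hyp()
  b <- best_design_for_n(hyp, accrual = 24, alpha = 0.10, power = 0.92, n = 73)
  expect_equal(b$n1, 44)
  expect_equal(b$c1, 0.240, tolerance = 1e-9)
  expect_equal(b$c, -1.281, tolerance = 5e-4)
  expect_equal(round(b$ESS0, 1), 61.3)
  # far too small a maximum sample size: no feasible design
  expect_null(best_design_for_n(hyp, accrual = 24, alpha = 0.10,
                                power = 0.90, n = 20))
})

test_that("uncalibrated search is deterministic and self-consistent", {
  hyp <- panc_hyp()
  d <- surv2stage(hyp, accrual = 24, alpha = 0.10, power = 0.90,
                  calibrate = FALSE)
  expect_s3_class(d, "surv2stage")
  expect_identical(d$adjustments, 0L)
  expect_lte(d$minimax$n, d$optimal$n)
  expect_lte(d$optimal$ESS0, d$minimax$ESS0)
  # every returned design re-verifies its operating characteristics
  for (des in list(d$minimax, d$optimal)) {
    t1 <- des$n1 / 24
    nm <- null_moments(hyp, t1)
    am <- alt_moments(hyp, t1)
    expect_lte(type_one_error(des$c1, des$c, nm$rho0), 0.10 + 1e-7)
    expect_gte(attained_power(des$c1, des$c, des$n1, des$n, nm, am),
               0.90 - 1e-7)
    expect_equal(des$ESS0,
                 des$n1 + (1 - des$PET) * (des$n - des$n1), tolerance = 1e-9)
  }
  # identical rerun
  d2 <- surv2stage(hyp, accrual = 24, alpha = 0.10, power = 0.90,
                   calibrate = FALSE)
  expect_identical(as.data.frame(d), as.data.frame(d2))
})

test_that("search is invariant to rescaling the time unit", {
  a <- surv2stage(tab2_hyp(), accrual = 30, alpha = 0.05, power = 0.90,
                  calibrate = FALSE)
  # months instead of years: tc = 12, accrual 30/12, same landmark survival
  hyp_m <- surv_hypothesis(tc = 12, s0 = 0.50, hr = 0.5)
  b <- surv2stage(hyp_m, accrual = 30 / 12, alpha = 0.05, power = 0.90,
                  calibrate = FALSE)
  for (f in c("n1", "n", "c1")) {
    expect_equal(a$minimax[[f]], b$minimax[[f]], tolerance = 1e-9)
    expect_equal(a$optimal[[f]], b$optimal[[f]], tolerance = 1e-9)
  }
  expect_equal(a$minimax$c, b$minimax$c, tolerance = 1e-6)
  expect_equal(a$minimax$ESS0, b$minimax$ESS0, tolerance = 1e-9)
  expect_equal(b$minimax$ETSL0, 12 * a$minimax$ETSL0, tolerance = 1e-6)
})

test_that("a vacuous power requirement returns the smallest allowed design", {
  d <- surv2stage(panc_hyp(), accrual = 24, alpha = 0.10, power = 0.05,
                  n_start = 5, calibrate = FALSE)
  expect_equal(d$minimax$n, 5)
  expect_equal(d$optimal$n, 5)
})
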