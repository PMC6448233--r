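test_that("scale recovery from a landmark survival probability", {
  expect_equal(scale_from_probability(0.50, 1, 1), 1 / log(2), tolerance = 1e-12)
  expect_equal(round(scale_from_probability(0.50, 1, 1), 4), 1.4427)
  expect_equal(scale_from_probability(exp(-1), 1, 1), 1.0, tolerance = 1e-12)
  expect_equal(scale_from_probability(0.35, 1, 1), 1 / (-log(0.35)),
               tolerance = 1e-12)
  expect_equal(round(scale_from_probability(0.35, 1, 1), 5), 0.95254)
})

test_that("scale/survival round-trip over a parameter grid", {
  for (p in c(0.05, 0.35, 0.5, 0.9)) for (t in c(0.5, 1, 3)) {
    for (k in c(0.25, 0.5, 1, 2)) {
      m <- weibull_survival(shape = k, surv = p, time = t)
      expect_equal(survival_at(m, t), p, tolerance = 1e-12)
      expect_equal(cumhaz_at(m, t), -log(p), tolerance = 1e-12)
    }
  }
})

test_that("survivor function identities", {
  m <- weibull_survival(shape = 0.5, surv = 0.10, time = 1)
  expect_identical(survival_at(m, 0), 1)
  expect_equal(cumhaz_at(m, 1), -log(0.10), tolerance = 1e-12)
  expect_equal(round(cumhaz_at(m, 1), 4), 2.3026)
  tt <- seq(0.1, 4, by = 0.1)
  expect_true(all(diff(survival_at(m, tt)) < 0))
  expect_equal(cumhaz_at(m, tt), -log(survival_at(m, tt)), tolerance = 1e-12)
  # density integrates to one
  for (k in c(0.5, 1, 2)) {
    mm <- weibull_survival(shape = k, scale = 1.3)
    expect_equal(integrate(function(t) density_at(mm, t), 0, Inf,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-7)
  }
})

test_that("hazard ratio conventions", {
  hyp <- surv_hypothesis(tc = 1, scale0 = 1.44, scale1 = 2.88)
  expect_equal(hazard_ratio(hyp), 0.5, tolerance = 1e-12)
  same <- surv_hypothesis(tc = 1, s0 = 0.4, s1 = 0.4)
  expect_equal(hazard_ratio(same), 1.0, tolerance = 1e-12)
  # unequal shapes: time-dependent ratio (k1/k0) t^(k1 - k0) at lambda0 = lambda1
  uneq <- surv_hypothesis(tc = 1, scale0 = 1, scale1 = 1, shape0 = 0.5, shape1 = 1)
  expect_equal(hazard_ratio(uneq, 0.25), 1.0, tolerance = 1e-12)
  expect_error(hazard_ratio(uneq, 0), "positive")
  # equal shapes: constant over a grid of times
  hr <- hazard_ratio(hyp, seq(0.2, 3, by = 0.4))
  expect_true(all(abs(hr - 0.5) < 1e-12))
})

test_that("domain errors name the offending argument", {
  expect_error(scale_from_probability(1.2, 1, 1), "surv")
  expect_error(scale_from_probability(0.5, -1, 1), "time")
  expect_error(scale_from_probability(0.5, 1, 0), "shape")
  expect_error(weibull_survival(shape = 1, scale = -2), "scale")
  m <- weibull_survival(shape = 1, scale = 1)
  expect_error(survival_at(m, -0.1), "t")
  expect_error(surv_hypothesis(tc = 1, s0 = 0.3, hr = 2,
                               shape0 = 0.5, shape1 = 1), "equal shapes")
})
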