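test_that("null variance of the final-look statistic telescopes", {
  hyp <- panc_hyp()
  for (t1 in c(0.4, 44 / 24, 10)) {
    nm <- null_moments(hyp, t1)
    expect_equal(nm$sigma02^2, 0.65, tolerance = 1e-10)
  }
})

test_that("exponential closed forms match the quadrature", {
  hyp <- panc_hyp()
  h0 <- -log(0.35); h1 <- -log(0.50)
  for (t1 in c(1, 44 / 24, 3)) {
    nm <- null_moments(hyp, t1)
    cf <- exp_null_var(h0, 1, t1)
    expect_equal(nm$sigma01^2, cf$s01sq, tolerance = 1e-8)
    expect_equal(nm$rho0, sqrt(cf$s01sq / cf$s02sq), tolerance = 1e-8)
  }
  nm <- null_moments(hyp, 44 / 24)
  expect_equal(round(nm$sigma01^2, 4), 0.5032)
  expect_equal(round(nm$rho0, 3), 0.880)

  am <- alt_moments(hyp, 44 / 24)
  cf <- exp_alt_p(h0, h1, 1)
  expect_equal(am$p$p1, cf$p1, tolerance = 1e-8)
  expect_equal(am$p$p0, cf$p0, tolerance = 1e-8)
  expect_equal(am$p$p00, cf$p00, tolerance = 1e-8)
  expect_equal(am$p$p01, cf$p01, tolerance = 1e-8)
  expect_equal(am$sigma12^2, wu_var(cf), tolerance = 1e-8)
  expect_equal(am$p$p1, 0.5, tolerance = 1e-10)  # -int G dS1 = 1 - S1(tc)
  expect_equal(am$p$p0, 0.7574, tolerance = 2e-4)
  expect_equal(round(am$omega, 4), -0.2573)
  expect_equal(round(am$sigma12^2, 4), 0.6730)
})

test_that("interim profile approaches the final profile as t1 grows", {
  hyp <- tab2_hyp()
  expect_equal(null_moments(hyp, Inf)$rho0, 1, tolerance = 1e-10)
  r <- vapply(c(2, 10, 100, 1000), function(t1) null_moments(hyp, t1)$rho0,
              numeric(1))
  expect_true(all(diff(r) > 0))
  expect_gt(r[4], 0.999)
})

test_that("identical hypotheses collapse the alternative moments", {
  hyp <- surv_hypothesis(tc = 1, s0 = 0.4, s1 = 0.4)
  am <- alt_moments(hyp, 1.5)
  nm <- null_moments(hyp, 1.5)
  expect_equal(am$omega, 0, tolerance = 1e-10)
  expect_equal(am$omega1, 0, tolerance = 1e-10)
  expect_equal(am$sigma12, nm$sigma02, tolerance = 1e-9)
  expect_equal(am$sigma11, nm$sigma01, tolerance = 1e-9)
  expect_equal(am$rho1, nm$rho0, tolerance = 1e-9)
})

test_that("interim censoring only reduces information", {
  # G1 <= G pointwise implies smaller variances and p-quantities
  for (hyp in list(panc_hyp(), tab2_hyp(), k05_hyp())) {
    for (t1 in c(0.5, 1.5, 3)) {
      nm <- null_moments(hyp, t1)
      am <- alt_moments(hyp, t1)
      expect_lt(nm$sigma01, nm$sigma02)
      expect_true(nm$rho0 > 0 && nm$rho0 < 1)
      expect_lt(am$sigma11, am$sigma12)
      expect_true(am$rho1 > 0 && am$rho1 < 1)
      expect_lt(am$p$p1f, am$p$p1)
      expect_lt(am$p$p0f, am$p$p0)
      expect_lt(am$p$p00f, am$p$p00)
      expect_lt(am$p$p01f, am$p$p01)
      expect_lt(am$omega, 0)   # improved survival: fewer events than expected
      expect_lt(am$omega1, 0)
    }
  }
})

test_that("Monte-Carlo oracle recovers the moment integrals", {
  hyp <- panc_hyp()
  t1 <- 44 / 24
  nm <- null_moments(hyp, t1)
  am <- alt_moments(hyp, t1)

  mc0 <- mc_logrank_moments(hyp, t1, 44, 73, under = "null",
                            reps = 40000L, seed = 4001)
  expect_lt(abs(mc0$mean[["W1"]]), 3 * mc0$se$mean[["W1"]])
  expect_lt(abs(mc0$mean[["W"]]), 3 * mc0$se$mean[["W"]])
  expect_lt(abs(mc0$var[["W1"]] - nm$sigma01^2), 4 * mc0$se$var[["W1"]])
  expect_lt(abs(mc0$var[["W"]] - nm$sigma02^2), 4 * mc0$se$var[["W"]])
  # true correlation carries the information fraction sqrt(n1/n) on top of
  # the sigma ratio used by the design calculus
  expect_equal(mc0$cor, nm$rho0 * sqrt(44 / 73), tolerance = 0.02)

  mc1 <- mc_logrank_moments(hyp, t1, 44, 73, under = "alternative",
                            reps = 40000L, seed = 4002)
  expect_lt(abs(mc1$mean[["W1"]] - sqrt(44) * am$omega1),
            3 * mc1$se$mean[["W1"]])
  expect_lt(abs(mc1$mean[["W"]] - sqrt(73) * am$omega),
            3 * mc1$se$mean[["W"]])
  expect_lt(abs(mc1$var[["W"]] - am$sigma12^2), 4 * mc1$se$var[["W"]])
  expect_lt(abs(mc1$var[["W1"]] - am$sigma11^2), 4 * mc1$se$var[["W1"]])
})
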