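#' Exact moments of the one-sample log-rank statistics
#'
#' For a two-stage trial with restricted follow-up, let `W1` and `W` be the
#' per-patient-normalised observed-minus-expected event counts at the
#' interim look (calendar time `t1`, first-stage patients only) and at the
#' final analysis (all patients followed through `tc`). The administrative
#' censoring survivor functions are `G(t) = I(t <= tc)` at the final
#' analysis and `G1(t) = max(0, 1 - t/t1) I(t <= tc)` at the interim, the
#' latter reflecting uniform enrolment of the first-stage patients over
#' `(0, t1)`.
#'
#' `null_moments` returns the null variances and correlation:
#' `sigma01^2 = -int G1 dS0`, `sigma02^2 = -int G dS0 = 1 - S0(tc)`, and
#' `rho0 = sigma01/sigma02`.
#'
#' `alt_moments` returns the mean scale factors `omega1 = p1f - p0f` and
#' `omega = p1 - p0` (so `E(W1) = sqrt(n1) omega1`, `E(W) = sqrt(n) omega`;
#' both negative when the alternative improves survival), the exact
#' variances under the alternative via Wu's formula
#' `sigma^2 = p1 - p1^2 - p0^2 + 2 p0 p1 + 2 p00 - 2 p01`
#' (interim version with the `G1`-weighted p-quantities), and
#' `rho1 = sigma11/sigma12`. The p-quantities are
#' `p1 = int G S1 dLambda1`, `p0 = int G S1 dLambda0`,
#' `p00 = int G S1 Lambda0 dLambda0`, `p01 = int G S1 Lambda0 dLambda1`,
#' with `p1f, p0f, p00f, p01f` replacing `G` by `G1`.
#'
#' All integrals are over `[0, tc]` by adaptive quadrature (split at the
#' kink of `G1` when `t1 < tc`).
#'
#' @param hypothesis A [surv_hypothesis()] object.
#' @param t1 Interim analysis calendar time (> 0), typically
#'   `n1 / accrual`. `t1 = Inf` gives the final-analysis profile.
#' @return `null_moments`: a list with `sigma01`, `sigma02`, `rho0` (class
#'   `"lr_moments_null"`). `alt_moments`: a list with `omega`, `omega1`,
#'   `sigma11`, `sigma12`, `rho1` and the p-quantities in `$p` (class
#'   `"lr_moments_alt"`).
#' @examples
#' hyp <- surv_hypothesis(tc = 1, s0 = 0.35, s1 = 0.50)
#' null_moments(hyp, t1 = 44 / 24)  # rho0 ~ 0.880
#' @export
null_moments <- function(hypothesis, t1) {
  check_interim_time(t1)
  tc <- hypothesis$tc
  m0 <- hypothesis$null
  s02sq <- 1 - survival_at(m0, tc)
  g1 <- interim_censor_fn(t1)
  s01sq <- integrate_tc(function(t) g1(t) * density_at(m0, t), tc, t1)
  structure(list(sigma01 = sqrt(s01sq), sigma02 = sqrt(s02sq),
                 rho0 = sqrt(s01sq / s02sq)),
            class = "lr_moments_null")
}

#' @rdname null_moments
#' @export
alt_moments <- function(hypothesis, t1) {
  check_interim_time(t1)
  tc <- hypothesis$tc
  m0 <- hypothesis$null
  m1 <- hypothesis$alt
  g1 <- interim_censor_fn(t1)
  pquant <- function(w) {
    list(
      p1  = integrate_tc(function(t) w(t) * density_at(m1, t), tc, t1),
      p0  = integrate_tc(function(t) w(t) * survival_at(m1, t) * hazard_at(m0, t), tc, t1),
      p00 = integrate_tc(function(t) w(t) * survival_at(m1, t) * cumhaz_at(m0, t) *
                           hazard_at(m0, t), tc, t1),
      p01 = integrate_tc(function(t) w(t) * survival_at(m1, t) * cumhaz_at(m0, t) *
                           hazard_at(m1, t), tc, t1)
    )
  }
  fin <- pquant(function(t) 1)
  int <- pquant(g1)
  wu <- function(q) q$p1 - q$p1^2 - q$p0^2 + 2 * q$p0 * q$p1 + 2 * q$p00 - 2 * q$p01
  s12sq <- wu(fin)
  s11sq <- wu(int)
  if (s11sq <= 0 || s12sq <= 0)
    stop("degenerate alternative variance (no events observable)", call. = FALSE)
  structure(list(omega = fin$p1 - fin$p0, omega1 = int$p1 - int$p0,
                 sigma11 = sqrt(s11sq), sigma12 = sqrt(s12sq),
                 rho1 = sqrt(s11sq / s12sq),
                 p = list(p1 = fin$p1, p0 = fin$p0, p00 = fin$p00, p01 = fin$p01,
                          p1f = int$p1, p0f = int$p0, p00f = int$p00, p01f = int$p01)),
            class = "lr_moments_alt")
}

check_interim_time <- function(t1) {
  if (!is.numeric(t1) || length(t1) != 1L || is.na(t1) || t1 <= 0)
    stop("`t1` must be a positive time (Inf allowed)", call. = FALSE)
  invisible(t1)
}

# survivor function of the interim follow-up bound t1 - tau, tau ~ U(0, t1);
# the I(t <= tc) factor is carried by the integration range
interim_censor_fn <- function(t1) {
  if (is.infinite(t1)) return(function(t) rep(1, length(t)))
  function(t) pmax(0, 1 - t / t1)
}

# adaptive quadrature over [0, tc], split at the G1 kink
integrate_tc <- function(f, tc, t1 = NULL) {
  brk <- c(0, if (!is.null(t1) && is.finite(t1) && t1 < tc) t1, tc)
  tot <- 0
  for (j in seq_len(length(brk) - 1L)) {
    r <- tryCatch(
      stats::integrate(f, brk[j], brk[j + 1L], rel.tol = 1e-11,
                       abs.tol = 1e-12, subdivisions = 500L),
      error = function(e) stop("quadrature failed on [", brk[j], ", ",
                               brk[j + 1L], "]: ", conditionMessage(e),
                               call. = FALSE))
    tot <- tot + r$value
  }
  tot
}

#' Monte-Carlo oracle for the log-rank moments
#'
#' Simulates the counting-process quantities behind `W1` and `W` directly
#' (per-patient observed times, event indicators and null cumulative-hazard
#' exposures) and returns their empirical moments with standard errors.
#' Used to validate the quadrature in [null_moments()] and [alt_moments()].
#' First-stage entry times are uniform on `(0, t1)`, matching the `G1`
#' profile assumed by the moment integrals.
#'
#' @param hypothesis A [surv_hypothesis()] object.
#' @param t1 Interim calendar time.
#' @param n1,n Stage-1 and total sample sizes.
#' @param under Generate event times from the `"null"` or `"alternative"`
#'   model (the expected-count process always uses the null hazard).
#' @param reps Number of simulated trials (>= 1e4 recommended).
#' @param seed Optional RNG seed.
#' @return List with components `mean` (of `W1`, `W`), `var`, `cor`, and
#'   `se` (standard errors of the means and, approximately, variances).
#' @export
mc_logrank_moments <- function(hypothesis, t1, n1, n,
                               under = c("null", "alternative"),
                               reps = 10000L, seed = NULL) {
  under <- match.arg(under)
  if (!is.null(seed)) set.seed(seed)
  tc <- hypothesis$tc
  m0 <- hypothesis$null
  mgen <- if (under == "null") m0 else hypothesis$alt
  W1 <- numeric(reps); W <- numeric(reps)
  chunk <- max(1L, min(reps, floor(2e6 / n)))
  done <- 0L
  while (done < reps) {
    R <- min(chunk, reps - done)
    T <- matrix(stats::rweibull(n * R, shape = mgen$shape, scale = mgen$scale), n, R)
    tau1 <- matrix(stats::runif(n1 * R, 0, t1), n1, R)
    T1 <- T[seq_len(n1), , drop = FALSE]
    fu1 <- pmin(tc, t1 - tau1)
    O1 <- pmin(T1, fu1)
    E1 <- colSums(cumhaz_at(m0, O1))
    W1[done + seq_len(R)] <- (colSums(T1 <= fu1) - E1) / sqrt(n1)
    Ef <- colSums(cumhaz_at(m0, pmin(T, tc)))
    W[done + seq_len(R)] <- (colSums(T <= tc) - Ef) / sqrt(n)
    done <- done + R
  }
  v1 <- stats::var(W1); v <- stats::var(W)
  list(mean = c(W1 = mean(W1), W = mean(W)),
       var = c(W1 = v1, W = v),
       cor = stats::cor(W1, W),
       se = list(mean = c(W1 = sqrt(v1 / reps), W = sqrt(v / reps)),
                 var = c(W1 = v1 * sqrt(2 / (reps - 1)),
                         W = v * sqrt(2 / (reps - 1)))))
}
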