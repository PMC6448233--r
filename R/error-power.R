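#' Type I error rate of a two-stage design
#'
#' The trial continues past the interim only when `Z1 < c1` and rejects the
#' null at the final analysis when `Z <= c`, so the type I error rate is
#' `P(Z1 <= c1, Z <= c | H0)`, the standard bivariate normal CDF at
#' `(c, c1)` with correlation `rho0`. The default method evaluates the
#' closed-form CDF ([pbvnorm()]); `method = "quadrature"` instead computes
#' the defining one-dimensional integral
#' `int_{-Inf}^{c} phi(t) Phi((c1 - rho0 t)/sqrt(1 - rho0^2)) dt`
#' by adaptive quadrature, kept as an independent cross-check.
#'
#' @param c1 Interim critical value (standard-normal scale; `Inf` removes
#'   the interim constraint).
#' @param c Final critical value.
#' @param rho0 Correlation of the two statistics under the null.
#' @param method `"bvnorm"` (default) or `"quadrature"`.
#' @return Rejection probability under the null.
#' @examples
#' type_one_error(0.240, -1.281, 0.880)  # ~0.10
#' @export
type_one_error <- function(c1, c, rho0, method = c("bvnorm", "quadrature")) {
  method <- match.arg(method)
  if (method == "bvnorm") return(pbvnorm(c, c1, rho0))
  if (abs(rho0) >= 1) return(pbvnorm(c, c1, rho0))  # degenerate limit
  n <- max(length(c1), length(c))
  c1 <- rep_len(c1, n); c <- rep_len(c, n)
  vapply(seq_len(n), function(i) {
    if (c[i] == -Inf) return(0)
    f <- function(t) stats::dnorm(t) *
      stats::pnorm((c1[i] - rho0 * t) / sqrt(1 - rho0^2))
    stats::integrate(f, -Inf, c[i], rel.tol = 1e-12, abs.tol = 1e-13,
                     subdivisions = 500L)$value
  }, numeric(1))
}

#' Asymptotic power of a two-stage design
#'
#' Under the alternative, `(Z1, Z)` is asymptotically bivariate normal with
#' correlation `rho1`; translating the boundaries to that scale gives
#' `c1~ = (sigma01/sigma11) (c1 - omega1 sqrt(n1) / sigma01)` and
#' `c~ = (sigma02/sigma12) (c - omega sqrt(n) / sigma02)`, and the power is
#' the bivariate normal CDF at `(c~, c1~)` with correlation `rho1`.
#'
#' @param c1,c Interim and final critical values.
#' @param n1,n Stage-1 and maximum sample sizes.
#' @param null_m,alt_m Moment sets from [null_moments()] and
#'   [alt_moments()] computed at `t1 = n1/accrual`.
#' @return Rejection probability under the alternative.
#' @export
attained_power <- function(c1, c, n1, n, null_m, alt_m) {
  if (alt_m$sigma11 <= 0 || alt_m$sigma12 <= 0)
    stop("non-positive alternative standard deviation", call. = FALSE)
  c1t <- (null_m$sigma01 / alt_m$sigma11) *
    (c1 - alt_m$omega1 * sqrt(n1) / null_m$sigma01)
  ct <- (null_m$sigma02 / alt_m$sigma12) *
    (c - alt_m$omega * sqrt(n) / null_m$sigma02)
  pbvnorm(ct, c1t, alt_m$rho1)
}

#' Final critical value attaining a target type I error rate
#'
#' The largest `c` with `type_one_error(c1, c, rho0) <= alpha` (the error
#' rate is strictly increasing in `c`). When `pnorm(c1) <= alpha` the
#' interim boundary already caps the error rate below `alpha` and no finite
#' boundary attains it; `NA` is returned for such elements.
#'
#' @param c1 Interim critical value(s); vectorised.
#' @param rho0 Null correlation between the interim and final statistics.
#' @param alpha One-sided significance level.
#' @param tol Bisection tolerance on `c`.
#' @return Vector of final critical values (`NA` where infeasible).
#' @examples
#' solve_final_critical(Inf, 0.9, 0.05)  # qnorm(0.05)
#' @export
solve_final_critical <- function(c1, rho0, alpha, tol = 1e-9) {
  check_prob_open(alpha, "alpha")
  n <- length(c1)
  out <- numeric(n)
  inf <- is.infinite(c1) & c1 > 0
  out[inf] <- stats::qnorm(alpha)
  feas <- !inf & (pnorm(c1) > alpha)
  out[!inf & !feas] <- NA_real_
  if (any(feas)) {
    cf <- c1[feas]
    lo <- rep(-15, length(cf)); hi <- rep(10, length(cf))
    while (max(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      ok <- pbvnorm(mid, cf, rho0) <= alpha
      lo[ok] <- mid[ok]
      hi[!ok] <- mid[!ok]
    }
    out[feas] <- (lo + hi) / 2
  }
  out
}
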