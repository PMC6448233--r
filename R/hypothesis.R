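#' Null and alternative survival hypotheses for a single-arm trial
#'
#' Defines the pair of Weibull models compared by a single-arm trial with a
#' survival endpoint: the historical (null) model and the hoped-for
#' (alternative) model, together with the clinically meaningful follow-up
#' time `tc` at which survival is evaluated. The test is one-sided:
#' `H0: S(tc) <= s0` against `H1: S(tc) > s0`, so under the alternative of
#' interest `s1 > s0` (equivalently, hazard ratio below 1 when the shapes
#' are equal).
#'
#' The alternative may be given as a landmark survival probability `s1` or
#' as a hazard ratio `hr = (lambda0/lambda1)^k` (equal shapes only), from
#' which the alternative scale is `lambda1 = lambda0 / hr^(1/k)`.
#'
#' @param tc Clinically meaningful follow-up time (> 0), e.g. 1 year.
#' @param s0,s1 Null and alternative survival probabilities at `tc`.
#' @param hr Hazard ratio of the alternative relative to the null
#'   (constant-in-time form, requires `shape0 == shape1`); used when `s1`
#'   is not given.
#' @param shape Common Weibull shape, used for both models unless
#'   `shape0`/`shape1` are given.
#' @param shape0,shape1 Shapes of the null and alternative models.
#' @param scale0,scale1 Scales of the two models; alternatives to
#'   `s0`/`s1`.
#' @return An object of class `"surv_hypothesis"`: a list with elements
#'   `null` and `alt` (both [weibull_survival()]) and `tc`.
#' @examples
#' # pancreatic cancer trial: exponential, S0(1) = 35%, S1(1) = 50%
#' hyp <- surv_hypothesis(tc = 1, s0 = 0.35, s1 = 0.50)
#' hazard_ratio(hyp)
#' @export
surv_hypothesis <- function(tc, s0 = NULL, s1 = NULL, hr = NULL,
                            shape = 1, shape0 = shape, shape1 = shape,
                            scale0 = NULL, scale1 = NULL) {
  check_positive(tc, "tc")
  null <- if (is.null(scale0)) {
    if (is.null(s0)) stop("supply `s0` or `scale0`", call. = FALSE)
    weibull_survival(shape0, surv = s0, time = tc)
  } else weibull_survival(shape0, scale = scale0)
  alt <- if (!is.null(scale1)) {
    weibull_survival(shape1, scale = scale1)
  } else if (!is.null(s1)) {
    weibull_survival(shape1, surv = s1, time = tc)
  } else if (!is.null(hr)) {
    if (shape0 != shape1)
      stop("`hr` specification requires equal shapes", call. = FALSE)
    check_positive(hr, "hr")
    weibull_survival(shape1, scale = null$scale / hr^(1 / shape1))
  } else stop("supply `s1`, `hr` or `scale1`", call. = FALSE)
  obj <- structure(list(null = null, alt = alt, tc = tc),
                   class = "surv_hypothesis")
  obj
}

#' Hazard ratio of the alternative relative to the null model
#'
#' With a common shape `k` the ratio is constant,
#' `Delta = (lambda0/lambda1)^k`; an improvement in survival corresponds to
#' `Delta < 1`. With different shapes the ratio depends on time,
#' `Delta(t) = (lambda0^k0 / lambda1^k1) * (k1 t^(k1-1)) / (k0 t^(k0-1))`,
#' and `t > 0` must be supplied.
#'
#' @param hypothesis A [surv_hypothesis()] object.
#' @param t Time at which to evaluate the ratio; optional when the shapes
#'   are equal.
#' @return The hazard ratio (positive scalar, or vector over `t`).
#' @export
hazard_ratio <- function(hypothesis, t = NULL) {
  m0 <- hypothesis$null; m1 <- hypothesis$alt
  if (m0$shape == m1$shape) {
    return(rep((m0$scale / m1$scale)^m0$shape, max(1L, length(t))))
  }
  if (is.null(t)) stop("`t` is required when the shapes differ", call. = FALSE)
  check_positive(t, "t")
  hazard_at(m1, t) / hazard_at(m0, t)
}

#' @export
print.surv_hypothesis <- function(x, ...) {
  cat("Single-arm survival hypotheses (one-sided)\n")
  cat(sprintf("  follow-up time tc = %g\n", x$tc))
  cat(sprintf("  H0: S(tc) <= %.4f   (k = %g, lambda = %.4f)\n",
              survival_at(x$null, x$tc), x$null$shape, x$null$scale))
  cat(sprintf("  H1: S(tc)  = %.4f   (k = %g, lambda = %.4f)\n",
              survival_at(x$alt, x$tc), x$alt$shape, x$alt$scale))
  if (x$null$shape == x$alt$shape)
    cat(sprintf("  hazard ratio Delta = %.4f\n", hazard_ratio(x)))
  invisible(x)
}
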