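#' Weibull survival model
#'
#' Constructs a Weibull event-time model parameterised by shape `k` and
#' scale `lambda`, with survivor function `S(t) = exp(-(t/lambda)^k)`.
#' The exponential model is the special case `k = 1`. Instead of the scale,
#' the model may be specified through a survival probability at a landmark
#' time (`surv` at `time`), from which the scale is recovered with
#' [scale_from_probability()].
#'
#' @param shape Weibull shape parameter `k` (> 0). `k < 1` gives a
#'   decreasing hazard, `k > 1` an increasing one.
#' @param scale Weibull scale parameter `lambda` (> 0), in time units.
#' @param surv,time Alternative specification: survival probability
#'   `surv` in (0, 1) at time `time` (> 0). Exactly one of `scale` and the
#'   (`surv`, `time`) pair must be given.
#' @return An object of class `"weibull_survival"` with elements `shape`
#'   and `scale`.
#' @examples
#' m <- weibull_survival(shape = 1, surv = 0.35, time = 1)
#' survival_at(m, 1)  # 0.35
#' @export
weibull_survival <- function(shape = 1, scale = NULL, surv = NULL, time = NULL) {
  check_positive(shape, "shape")
  if (is.null(scale)) {
    if (is.null(surv) || is.null(time))
      stop("supply either `scale` or both `surv` and `time`", call. = FALSE)
    scale <- scale_from_probability(surv, time, shape)
  } else {
    if (!is.null(surv))
      stop("supply either `scale` or `surv`/`time`, not both", call. = FALSE)
    check_positive(scale, "scale")
  }
  structure(list(shape = shape, scale = scale), class = "weibull_survival")
}

#' Weibull scale from a landmark survival probability
#'
#' Inverts `S(t) = exp(-(t/lambda)^k)` for the scale:
#' `lambda = t / (-log(surv))^(1/k)`.
#'
#' @param surv Survival probability in (0, 1).
#' @param time Landmark time (> 0).
#' @param shape Weibull shape (> 0).
#' @return The scale `lambda`.
#' @examples
#' scale_from_probability(0.50, 1, 1)  # 1.4427
#' @export
scale_from_probability <- function(surv, time, shape) {
  check_prob_open(surv, "surv")
  check_positive(time, "time")
  check_positive(shape, "shape")
  time / (-log(surv))^(1 / shape)
}

#' Evaluate a Weibull survival model
#'
#' `survival_at`, `cumhaz_at`, `hazard_at` and `density_at` evaluate the
#' survivor function `S(t)`, cumulative hazard `Lambda(t) = (t/lambda)^k`,
#' hazard `k/lambda (t/lambda)^(k-1)` and density `f(t) = S(t) h(t)`.
#'
#' @param model A [weibull_survival()] object.
#' @param t Vector of times (>= 0; the hazard and density require `t > 0`
#'   when `shape != 1`).
#' @return Numeric vector of the same length as `t`.
#' @export
survival_at <- function(model, t) {
  check_nonneg(t, "t")
  exp(-(t / model$scale)^model$shape)
}

#' @rdname survival_at
#' @export
cumhaz_at <- function(model, t) {
  check_nonneg(t, "t")
  (t / model$scale)^model$shape
}

#' @rdname survival_at
#' @export
hazard_at <- function(model, t) {
  check_nonneg(t, "t")
  model$shape / model$scale * (t / model$scale)^(model$shape - 1)
}

#' @rdname survival_at
#' @export
density_at <- function(model, t) {
  survival_at(model, t) * hazard_at(model, t)
}

#' @export
print.weibull_survival <- function(x, ...) {
  cat(sprintf("Weibull survival model: shape k = %g, scale lambda = %g\n",
              x$shape, x$scale))
  invisible(x)
}

# --- argument checks (shared) ---------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be a finite positive number", name), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  invisible(x)
}

check_prob_open <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop(sprintf("`%s` must lie strictly between 0 and 1", name), call. = FALSE)
  invisible(x)
}
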