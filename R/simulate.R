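#' One-sample log-rank statistic
#'
#' Compares the observed number of events `O = sum(status)` with the
#' expected number under a reference (null) model,
#' `E = sum(Lambda0(time_i))`, where `Lambda0` is the null cumulative
#' hazard evaluated at each patient's observed (possibly censored) time.
#' The statistic is `Z = (O - E)/sqrt(E)`; small values indicate better
#' survival than the reference.
#'
#' @param time Observed times (event or censoring), non-negative.
#' @param status Event indicators (1 = event, 0 = censored).
#' @param null_model Reference [weibull_survival()] model.
#' @return List with `observed`, `expected` and `statistic`. When the
#'   total exposure is zero (`E = 0`) the statistic is undefined and
#'   returned as `NA`.
#' @examples
#' m0 <- weibull_survival(shape = 1, scale = 1)
#' one_sample_logrank(c(0.5, 1, 2), c(1, 0, 1), m0)
#' @export
one_sample_logrank <- function(time, status, null_model) {
  check_nonneg(time, "time")
  if (length(status) != length(time))
    stop("`time` and `status` must have equal length", call. = FALSE)
  O <- sum(status != 0)
  E <- sum(cumhaz_at(null_model, time))
  z <- if (E > 0) (O - E) / sqrt(E) else NA_real_
  list(observed = O, expected = E, statistic = z)
}

#' Simulate operating characteristics of a two-stage survival design
#'
#' Simulates single-arm trials under uniform accrual at rate `accrual`.
#' With the default `entry = "staged"` the first-stage patients enter
#' uniformly over `(0, t1)` with `t1 = n1/accrual` and the second-stage
#' patients over `(t1, n/accrual)`; this matches the interim censoring
#' profile `G1(t) = max(0, 1 - t/t1)` used by the moment integrals.
#' `entry = "pooled"` instead draws all `n` entry times uniformly over the
#' whole accrual period and takes the first `n1` arrivals for the interim,
#' so the interim can include patients with little or no follow-up; the
#' interim look then carries slightly less information than `G1` assumes.
#' Event times are Weibull from the null or the alternative model; every
#' patient is administratively censored at the follow-up horizon `tc`.
#' The interim statistic uses observed times
#' `min(T_i, tc, max(0, t1 - tau_i))`; the trial stops for futility when
#' `Z1 >= c1`, otherwise the final statistic is computed with all `n`
#' patients followed through `tc`, and the null is rejected when
#' `Z <= c`. An interim with zero expected events (no exposure) is treated
#' as "continue".
#'
#' @param design A `"surv2stage_design"` object, or a numeric vector
#'   `c(n1, n, c1, c)`.
#' @param hypothesis A [surv_hypothesis()] object.
#' @param accrual Accrual rate.
#' @param under Simulate under the `"null"` (type I error rate) or the
#'   `"alternative"` (power) model.
#' @param reps Number of simulated trials.
#' @param seed Optional RNG seed (same seed, same result).
#' @param entry Entry-time model: `"staged"` (default) or `"pooled"`, see
#'   Details.
#' @param chunk Trials simulated per vectorised block.
#' @return An object of class `"surv2stage_sim"`: list with `reject` (the
#'   rejection fraction), `early_stop`, `reps`, `under`, `seed`.
#' @export
simulate_oc <- function(design, hypothesis, accrual,
                        under = c("null", "alternative"),
                        reps = 100000L, seed = NULL,
                        entry = c("staged", "pooled"), chunk = 20000L) {
  under <- match.arg(under)
  entry <- match.arg(entry)
  d <- as_design_vector(design)
  stopifnot(inherits(hypothesis, "surv_hypothesis"))
  check_positive(accrual, "accrual")
  if (!is.null(seed)) set.seed(seed)
  n1 <- d[["n1"]]; n <- d[["n"]]; c1 <- d[["c1"]]; cf <- d[["c"]]
  tc <- hypothesis$tc
  m0 <- hypothesis$null
  mgen <- if (under == "null") m0 else hypothesis$alt
  t1 <- n1 / accrual
  ta <- n / accrual
  rej <- 0; early <- 0; left <- as.integer(reps)
  chunk <- max(1L, min(chunk, floor(4e6 / n)))
  while (left > 0L) {
    R <- min(chunk, left); left <- left - R
    if (entry == "staged") {
      tau <- rbind(matrix(stats::runif(n1 * R, 0, t1), n1, R),
                   matrix(stats::runif((n - n1) * R, t1, ta), n - n1, R))
    } else {
      tau <- matrix(stats::runif(n * R, 0, ta), n, R)
      tau <- apply(tau, 2L, sort)
    }
    T <- matrix(stats::rweibull(n * R, shape = mgen$shape, scale = mgen$scale),
                n, R)
    T1 <- T[seq_len(n1), , drop = FALSE]
    fu1 <- pmin(tc, pmax(0, t1 - tau[seq_len(n1), , drop = FALSE]))
    E1 <- colSums(cumhaz_at(m0, pmin(T1, fu1)))
    Z1 <- ifelse(E1 > 0, (colSums(T1 <= fu1) - E1) / sqrt(E1), -Inf)
    go <- Z1 < c1
    early <- early + sum(!go)
    if (any(go)) {
      Tg <- T[, go, drop = FALSE]
      E <- colSums(cumhaz_at(m0, pmin(Tg, tc)))
      Z <- (colSums(Tg <= tc) - E) / sqrt(E)
      rej <- rej + sum(Z <= cf)
    }
  }
  structure(list(reject = rej / reps, early_stop = early / reps,
                 reps = as.integer(reps), under = under, seed = seed,
                 design = d),
            class = "surv2stage_sim")
}

#' Replicated operating characteristics with an empirical interval
#'
#' Repeats [simulate_oc()] `outer` times with `inner` trials each and
#' summarises the spread of the estimates by their 2.5% and 97.5%
#' empirical percentiles.
#'
#' @inheritParams simulate_oc
#' @param outer Number of independent estimates (>= 2).
#' @param inner Trials per estimate.
#' @return A `"surv2stage_sim"` object whose `reject`/`early_stop` are the
#'   means over the outer estimates, with an added `interval` element
#'   (2.5/97.5 percentiles of the rejection fraction).
#' @export
replicate_interval <- function(design, hypothesis, accrual,
                               under = c("null", "alternative"),
                               outer = 1000L, inner = 10000L, seed = NULL) {
  under <- match.arg(under)
  if (outer < 2L) stop("`outer` must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2^31 - 2, outer)
  est <- vapply(seq_len(outer), function(i) {
    s <- simulate_oc(design, hypothesis, accrual, under = under,
                     reps = inner, seed = seeds[i])
    c(s$reject, s$early_stop)
  }, numeric(2))
  out <- structure(list(reject = mean(est[1, ]), early_stop = mean(est[2, ]),
                        reps = as.integer(outer) * as.integer(inner),
                        under = under, seed = seed,
                        design = as_design_vector(design),
                        interval = stats::quantile(est[1, ], c(0.025, 0.975),
                                                   names = FALSE)),
                   class = "surv2stage_sim")
  out
}

as_design_vector <- function(design) {
  if (inherits(design, "surv2stage_design"))
    return(c(n1 = design$n1, n = design$n, c1 = design$c1, c = design$c))
  if (is.numeric(design) && length(design) == 4L) {
    d <- as.numeric(design)
    names(d) <- c("n1", "n", "c1", "c")
    if (d[["n1"]] < 1 || d[["n"]] <= d[["n1"]])
      stop("design requires 1 <= n1 < n", call. = FALSE)
    return(d)
  }
  stop("`design` must be a surv2stage_design or c(n1, n, c1, c)",
       call. = FALSE)
}

#' @export
print.surv2stage_sim <- function(x, ...) {
  cat(sprintf("simulated %s: %s = %.4f, early stop = %.4f (%s reps)\n",
              x$under,
              if (x$under == "null") "type I error" else "power",
              x$reject, x$early_stop, format(x$reps, big.mark = ",")))
  if (!is.null(x$interval))
    cat(sprintf("  95%% interval of estimates: (%.4f, %.4f)\n",
                x$interval[1], x$interval[2]))
  invisible(x)
}
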