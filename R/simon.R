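#' Exact operating characteristics of a Simon two-stage binomial design
#'
#' For the design `(n1, r1, n, r)` the trial stops for futility when the
#' stage-1 response count `X1 <= r1`; the null is rejected when `X1 > r1`
#' and the total count `X > r`. At response probability `p` the rejection
#' probability is
#' `sum_{x1 = r1+1}^{n1} dbinom(x1; n1, p) P(X2 > r - x1; n2, p)`
#' and the early-termination probability is `pbinom(r1; n1, p)`.
#'
#' @param n1,r1 Stage-1 sample size and futility boundary.
#' @param n,r Total sample size and final boundary.
#' @param p Response probability.
#' @return List with `reject` and `PET`.
#' @examples
#' simon_oc(43, 14, 72, 30, 0.35)  # PET = 0.4365
#' @export
simon_oc <- function(n1, r1, n, r, p) {
  check_prob_open(p, "p")
  if (r1 < 0 || r1 > n1 || n1 >= n || r < r1)
    stop("invalid design: need 0 <= r1 <= n1 < n and r >= r1", call. = FALSE)
  list(reject = simon_reject_prob(r1, n1, r, n - n1, p),
       PET = pbinom(r1, n1, p))
}

simon_reject_prob <- function(r1, n1, r, n2, p) {
  if (r1 >= n1) return(0)
  x1 <- (r1 + 1):n1
  tail2 <- ifelse(r - x1 < 0, 1, 1 - pbinom(pmax(r - x1, -1), n2, p))
  sum(dbinom(x1, n1, p) * tail2)
}

#' Simon two-stage minimax and optimal designs
#'
#' Exhaustive exact-binomial search over `(n, n1, r1, r)` for designs with
#' type I error rate at most `alpha` and power at least `power` comparing
#' response probabilities `p0` (null) and `p1` (alternative). For each
#' `(n, n1, r1)` the smallest final boundary `r` controlling the error
#' rate is found (the rejection probability is decreasing in `r`) and the
#' power checked there. The optimal design minimises the null expected
#' sample size `ESS0 = n1 + (1 - PET) n2`; the minimax design minimises
#' `n`, with ties broken by `ESS0`.
#'
#' When `accrual` and `tc` are supplied, expected-study-length metrics are
#' attached to both designs via [simon_study_length()], in both the
#' suspended-accrual and the interim-accrual variants.
#'
#' @param p0,p1 Null and alternative response probabilities (`p0 < p1`).
#' @param alpha One-sided type I error rate.
#' @param power Nominal power.
#' @param nmax Largest total sample size searched.
#' @param accrual,tc Optional accrual rate and response-assessment time
#'   for study-length metrics.
#' @return An object of class `"simon2stage"` with elements `minimax` and
#'   `optimal` (each class `"simon_design"`).
#' @examples
#' \donttest{
#' s <- simon2stage(0.10, 0.25, alpha = 0.05, power = 0.80, nmax = 60)
#' s$optimal  # (n1, r1, n, r) = (18, 2, 43, 7), ESS0 = 24.7
#' }
#' @export
simon2stage <- function(p0, p1, alpha = 0.05, power = 0.80, nmax = 150L,
                        accrual = NULL, tc = NULL) {
  check_prob_open(p0, "p0"); check_prob_open(p1, "p1")
  check_prob_open(alpha, "alpha"); check_prob_open(power, "power")
  if (p0 >= p1) stop("`p0` must be smaller than `p1`", call. = FALSE)
  beta <- 1 - power
  minimax <- NULL; optimal <- NULL
  for (n in 2:nmax) {
    for (n1 in seq_len(n - 1L)) {
      # a candidate can no longer beat the optimal once n1 alone exceeds it
      if (!is.null(optimal) && !is.null(minimax) && n > minimax$n &&
          n1 >= optimal$ESS0) break
      n2 <- n - n1
      for (r1 in 0:n1) {
        if (pbinom(r1, n1, p1) > beta) break  # stage-1 alone sinks the power
        r <- smallest_final_boundary(r1, n1, n2, p0, alpha)
        pw <- simon_reject_prob(r1, n1, r, n2, p1)
        if (pw < power) next
        PET <- pbinom(r1, n1, p0)
        ess <- n1 + (1 - PET) * n2
        cand <- structure(list(n1 = n1, r1 = r1, n = n, r = r, PET = PET,
                               ESS0 = ess,
                               tie = simon_reject_prob(r1, n1, r, n2, p0),
                               power = pw, p0 = p0, p1 = p1),
                          class = "simon_design")
        if (is.null(minimax) || (n == minimax$n && ess < minimax$ESS0))
          minimax <- cand
        if (is.null(optimal) || ess < optimal$ESS0)
          optimal <- cand
      }
    }
  }
  if (is.null(minimax))
    stop("no feasible Simon design up to nmax = ", nmax, call. = FALSE)
  if (!is.null(accrual) && !is.null(tc)) {
    minimax <- attach_study_length(minimax, accrual, tc)
    optimal <- attach_study_length(optimal, accrual, tc)
  }
  structure(list(minimax = minimax, optimal = optimal,
                 p0 = p0, p1 = p1, alpha = alpha, power = power,
                 accrual = accrual, tc = tc),
            class = "simon2stage")
}

# smallest r with exact TIE <= alpha (TIE decreasing in r); bisection
smallest_final_boundary <- function(r1, n1, n2, p0, alpha) {
  n <- n1 + n2
  if (simon_reject_prob(r1, n1, r1, n2, p0) <= alpha) return(r1)
  lo <- r1; hi <- n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (simon_reject_prob(r1, n1, mid, n2, p0) <= alpha) hi <- mid else lo <- mid
  }
  hi
}

#' Expected study length of a Simon design under the null
#'
#' With accrual rate `theta`, stage lengths are `t1 = n1/theta` and
#' `t2 = n2/theta`, and each stage adds the response-assessment time `tc`.
#' Without interim accrual the trial suspends enrolment during the stage-1
#' assessment:
#' `ESS0 = n1 + (1 - PET) n2` and
#' `ETSL0 = (t1 + tc) + (1 - PET) (t2 + tc)`.
#' With interim accrual, enrolment continues during the assessment, so
#' `theta tc` extra patients are always enrolled:
#' `ESS0 = n1 + theta tc + (1 - PET) (n2 - theta tc)` and
#' `ETSL0 = (t1 + tc) + (1 - PET) t2`.
#' The interim-accrual formulas are applied as stated; when
#' `n2 < theta tc` (the second stage shorter than the assessment window) a
#' warning is emitted.
#'
#' @param design A `"simon_design"` object (from [simon2stage()]).
#' @param accrual Accrual rate `theta`.
#' @param tc Response assessment time.
#' @param interim_accrual Continue enrolment during the interim assessment?
#' @return List with `ESS0` and `ETSL0`.
#' @export
simon_study_length <- function(design, accrual, tc, interim_accrual = FALSE) {
  check_positive(accrual, "accrual"); check_positive(tc, "tc")
  n1 <- design$n1; n2 <- design$n - design$n1; PET <- design$PET
  t1 <- n1 / accrual; t2 <- n2 / accrual
  if (!interim_accrual) {
    list(ESS0 = n1 + (1 - PET) * n2,
         ETSL0 = (t1 + tc) + (1 - PET) * (t2 + tc))
  } else {
    if (n2 < accrual * tc)
      warning("interim accrual overruns stage 2 (n2 < accrual * tc); ",
              "formulas applied as stated")
    list(ESS0 = n1 + accrual * tc + (1 - PET) * (n2 - accrual * tc),
         ETSL0 = (t1 + tc) + (1 - PET) * t2)
  }
}

attach_study_length <- function(d, accrual, tc) {
  no <- simon_study_length(d, accrual, tc, interim_accrual = FALSE)
  ia <- simon_study_length(d, accrual, tc, interim_accrual = TRUE)
  d$ETSL0 <- no$ETSL0
  d$ESS0_interim <- ia$ESS0
  d$ETSL0_interim <- ia$ETSL0
  d
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf("Simon design (n1, r1, n, r) = (%d, %d, %d, %d)\n",
              x$n1, x$r1, x$n, x$r))
  cat(sprintf("  PET = %.4f, ESS0 = %.1f, exact TIE = %.4f, power = %.4f\n",
              x$PET, x$ESS0, x$tie, x$power))
  if (!is.null(x$ETSL0))
    cat(sprintf("  ETSL0 = %.2f; with interim accrual: ESS0 = %.1f, ETSL0 = %.2f\n",
                x$ETSL0, x$ESS0_interim, x$ETSL0_interim))
  invisible(x)
}

#' @export
print.simon2stage <- function(x, ...) {
  cat(sprintf("Simon two-stage designs for p0 = %g vs p1 = %g (alpha = %g, power = %g)\n\n",
              x$p0, x$p1, x$alpha, x$power))
  cat("Minimax:\n"); print(x$minimax)
  cat("\nOptimal:\n"); print(x$optimal)
  invisible(x)
}
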