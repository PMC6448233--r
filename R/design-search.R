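#' Two-stage minimax and optimal designs with a survival endpoint
#'
#' Searches for single-arm two-stage designs `(n1, n, c1, c)` using the
#' one-sample log-rank test with restricted follow-up. For each total
#' sample size `n` (from `n_start` upwards) and each stage-1 size
#' `n1 = 1, ..., n-1`, every interim boundary `c1` on the grid is paired
#' with the largest final boundary `c` holding the type I error rate at
#' `alpha`; combinations whose asymptotic power reaches the nominal level
#' are candidates, and the candidate with the smallest expected sample size
#' under the null, `ESS0 = n1 + (1 - PET) n2` with `PET = 1 - pnorm(c1)`,
#' is the best design for that `n`. The minimax design is the best design
#' at the smallest feasible `n`; the optimal design minimises `ESS0` over
#' `n`. The `n`-scan stops once the current `ESS0` exceeds `stop_factor`
#' times the smallest `ESS0` seen.
#'
#' Because the bivariate normal law of `(Z1, Z)` is asymptotic, the power
#' of the selected designs is optimistic in small samples. With
#' `calibrate = TRUE` (the default) both selected designs are checked by
#' trial simulation ([simulate_oc()], `sim_reps` replicates); if either
#' falls short of the nominal power the search is repeated with the
#' nominal level raised by one percentage point, and so on until both
#' simulated powers meet the original nominal level.
#'
#' @param hypothesis A [surv_hypothesis()] object.
#' @param accrual Accrual rate `theta` (patients per time unit).
#' @param alpha One-sided type I error rate.
#' @param power Nominal power `1 - beta`.
#' @param c1_grid Grid of interim critical values (default -0.3 to 1.6 in
#'   steps of 0.005).
#' @param n_start Smallest total sample size tried.
#' @param n_max Safety cap on `n`.
#' @param stop_factor Stop scanning when `ESS0(n)` exceeds this multiple of
#'   the running minimum (default 1.10).
#' @param calibrate Run the simulation-based power calibration loop.
#' @param sim_reps Replicates per simulated power estimate in the
#'   calibration loop.
#' @param max_adjust Cap on the number of one-point nominal-power raises.
#' @param seed RNG seed for the calibration simulations.
#' @param verbose Print progress per `n`.
#' @return An object of class `"surv2stage"`: list with elements `minimax`
#'   and `optimal` (class `"surv2stage_design"`), `candidates` (data frame
#'   of best designs per `n` at the final nominal level), `adjustments`
#'   (number of one-point raises applied), `sim_power` (simulated powers of
#'   the returned designs when calibrated), and the problem definition.
#' @examples
#' \donttest{
#' hyp <- surv_hypothesis(tc = 1, s0 = 0.35, s1 = 0.50)
#' d <- surv2stage(hyp, accrual = 24, alpha = 0.10, power = 0.90,
#'                 calibrate = FALSE)
#' d$minimax
#' }
#' @export
surv2stage <- function(hypothesis, accrual, alpha = 0.05, power = 0.80,
                       c1_grid = seq(-0.3, 1.6, by = 0.005),
                       n_start = 5L, n_max = 500L, stop_factor = 1.10,
                       calibrate = TRUE, sim_reps = 100000L,
                       max_adjust = 20L, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(hypothesis, "surv_hypothesis"))
  check_prob_open(alpha, "alpha")
  check_prob_open(power, "power")
  check_positive(accrual, "accrual")
  c1_grid <- round(sort(c1_grid), 10)
  if (!is.null(seed)) set.seed(seed)
  sim_seeds <- if (calibrate) sample.int(2^31 - 2, 2L * (max_adjust + 1L)) else NULL

  j <- 0L
  repeat {
    target <- power + 0.01 * j
    if (target >= 1)
      stop("power calibration exceeded 100%: design problem infeasible",
           call. = FALSE)
    res <- run_design_scan(hypothesis, accrual, alpha, target, c1_grid,
                           n_start, n_max, stop_factor, verbose)
    if (!calibrate) { sim_pow <- NULL; break }
    pm <- simulate_oc(res$minimax, hypothesis, accrual, under = "alternative",
                      reps = sim_reps, seed = sim_seeds[2L * j + 1L])
    po <- simulate_oc(res$optimal, hypothesis, accrual, under = "alternative",
                      reps = sim_reps, seed = sim_seeds[2L * j + 2L])
    sim_pow <- c(minimax = pm$reject, optimal = po$reject)
    if (verbose)
      message(sprintf("calibration %d: simulated power %.4f (minimax), %.4f (optimal)",
                      j, pm$reject, po$reject))
    if (pm$reject >= power && po$reject >= power) break
    j <- j + 1L
    if (j > max_adjust)
      stop("power calibration did not converge within `max_adjust` raises",
           call. = FALSE)
  }

  structure(list(minimax = res$minimax, optimal = res$optimal,
                 candidates = res$candidates, adjustments = j,
                 sim_power = sim_pow,
                 problem = list(hypothesis = hypothesis, accrual = accrual,
                                alpha = alpha, power = power,
                                c1_grid = c1_grid, n_start = n_start,
                                n_max = n_max, stop_factor = stop_factor,
                                calibrate = calibrate, sim_reps = sim_reps,
                                seed = seed),
                 call = match.call()),
            class = "surv2stage")
}

# Steps 1-2: deterministic scan over n at a fixed nominal level
run_design_scan <- function(hypothesis, accrual, alpha, target, c1_grid,
                            n_start, n_max, stop_factor, verbose = FALSE) {
  cache <- new.env(parent = emptyenv())
  pet <- 1 - pnorm(c1_grid)
  minimax <- NULL
  cand <- list()
  n <- max(2L, as.integer(n_start))
  repeat {
    b <- scan_one_n(n, hypothesis, accrual, alpha, target, c1_grid, pet, cache)
    if (!is.null(b)) {
      cand[[length(cand) + 1L]] <- b
      if (is.null(minimax)) minimax <- b
      ess <- vapply(cand, `[[`, 0, "ESS0")
      if (verbose) message(sprintf("n = %d: ESS0 = %.2f", n, b$ESS0))
      if (b$ESS0 >= stop_factor * min(ess)) break
    }
    n <- n + 1L
    if (n > n_max)
      stop("no feasible design up to n_max = ", n_max, call. = FALSE)
  }
  ess <- vapply(cand, `[[`, 0, "ESS0")
  optimal <- cand[[which.min(ess)]]
  candidates <- do.call(rbind, lapply(cand, function(d)
    data.frame(n1 = d$n1, n = d$n, c1 = d$c1, c = d$c, PET = d$PET,
               ESS0 = d$ESS0, ETSL0 = d$ETSL0, power = d$power)))
  list(minimax = minimax, optimal = optimal, candidates = candidates)
}

# best design at one n: min ESS0 over (n1, c1) meeting the power target;
# ties resolved toward smaller n1, then smaller c1 (scan order)
scan_one_n <- function(n, hypothesis, accrual, alpha, target, c1_grid, pet,
                       cache) {
  best <- NULL
  for (n1 in seq_len(n - 1L)) {
    e <- stage1_quantities(n1, hypothesis, accrual, alpha, c1_grid, cache)
    ct <- (e$nm$sigma02 / e$am$sigma12) *
      (e$cvec - e$am$omega * sqrt(n) / e$nm$sigma02)
    pw <- pbvnorm(ct, e$c1t, e$am$rho1)
    ok <- !is.na(e$cvec) & pw >= target
    if (!any(ok)) next
    ess <- n1 + (1 - pet[ok]) * (n - n1)
    jj <- which.min(ess)
    if (is.null(best) || ess[jj] < best$ESS0) {
      idx <- which(ok)[jj]
      met <- design_metrics(n1, n, c1_grid[idx], accrual, hypothesis$tc)
      best <- new_design(n1, n, c1_grid[idx], e$cvec[idx], met,
                         power = pw[idx],
                         tie = pbvnorm(e$cvec[idx], c1_grid[idx], e$nm$rho0))
    }
  }
  best
}

# per-n1 moments, solved final boundaries and interim boundary transforms;
# memoised because they do not depend on n
stage1_quantities <- function(n1, hypothesis, accrual, alpha, c1_grid, cache) {
  key <- as.character(n1)
  e <- cache[[key]]
  if (!is.null(e)) return(e)
  t1 <- n1 / accrual
  nm <- null_moments(hypothesis, t1)
  am <- alt_moments(hypothesis, t1)
  cvec <- solve_final_critical(c1_grid, nm$rho0, alpha)
  c1t <- (nm$sigma01 / am$sigma11) *
    (c1_grid - am$omega1 * sqrt(n1) / nm$sigma01)
  e <- list(nm = nm, am = am, cvec = cvec, c1t = c1t)
  cache[[key]] <- e
  e
}

new_design <- function(n1, n, c1, c, metrics, power = NA_real_,
                       tie = NA_real_) {
  structure(list(n1 = n1, n = n, c1 = c1, c = c, PET = metrics$PET,
                 ESS0 = metrics$ESS0, ETSL0 = metrics$ETSL0,
                 power = power, tie = tie),
            class = "surv2stage_design")
}

#' Best design at a fixed maximum sample size
#'
#' Runs the inner search of [surv2stage()] for a single `n`: all stage-1
#' sizes and interim boundaries are scanned, the final boundary solved for
#' level `alpha`, and the smallest-`ESS0` combination with asymptotic power
#' at least `power` returned.
#'
#' @inheritParams surv2stage
#' @param n Total (maximum) sample size.
#' @return A `"surv2stage_design"` object, or `NULL` when no combination at
#'   this `n` reaches the nominal power.
#' @export
best_design_for_n <- function(hypothesis, accrual, alpha, power, n,
                              c1_grid = seq(-0.3, 1.6, by = 0.005)) {
  stopifnot(inherits(hypothesis, "surv_hypothesis"), n >= 2)
  c1_grid <- round(sort(c1_grid), 10)
  scan_one_n(as.integer(n), hypothesis, accrual, alpha, power, c1_grid,
             1 - pnorm(c1_grid), new.env(parent = emptyenv()))
}

#' Null operating characteristics of a survival two-stage design
#'
#' Under the null the interim statistic is asymptotically standard normal,
#' so the probability of early termination is `PET = 1 - pnorm(c1)`. The
#' expected sample size is `ESS0 = n1 + (1 - PET) (n - n1)`. A trial
#' stopped at the interim ends at the stage-1 accrual time `t1 = n1/theta`;
#' a continuing trial runs to `n/theta + tc`, so the expected total study
#' length is `ETSL0 = t1 + (1 - PET) (t2 + tc)` with `t2 = (n - n1)/theta`.
#'
#' @param n1,n Stage-1 and maximum sample sizes.
#' @param c1 Interim critical value.
#' @param accrual Accrual rate (patients per time unit).
#' @param tc Follow-up time.
#' @return List with `PET`, `ESS0`, `ETSL0`.
#' @examples
#' design_metrics(44, 73, 0.240, accrual = 24, tc = 1)
#' @export
design_metrics <- function(n1, n, c1, accrual, tc) {
  PET <- 1 - pnorm(c1)
  t1 <- n1 / accrual
  t2 <- (n - n1) / accrual
  list(PET = PET,
       ESS0 = n1 + (1 - PET) * (n - n1),
       ETSL0 = t1 + (1 - PET) * (t2 + tc))
}

#' @export
print.surv2stage_design <- function(x, ...) {
  cat(sprintf("two-stage design: n1 = %d, n = %d, c1 = %.3f, c = %.3f\n",
              x$n1, x$n, x$c1, x$c))
  cat(sprintf("  PET = %.4f, ESS0 = %.1f, ETSL0 = %.2f\n",
              x$PET, x$ESS0, x$ETSL0))
  if (!is.na(x$power))
    cat(sprintf("  asymptotic power = %.4f, type I error = %.4f\n",
                x$power, x$tie))
  invisible(x)
}

#' @export
print.surv2stage <- function(x, ...) {
  p <- x$problem
  cat("Two-stage designs, survival endpoint (one-sample log-rank,",
      "restricted follow-up)\n")
  cat(sprintf("  alpha = %g (one-sided), nominal power = %g, accrual = %g/time unit\n",
              p$alpha, p$power, p$accrual))
  if (x$adjustments > 0L)
    cat(sprintf("  power calibrated by simulation: nominal level raised %d x 1%%\n",
                x$adjustments))
  cat("\nMinimax design:\n")
  print(x$minimax)
  cat("\nOptimal design:\n")
  print(x$optimal)
  if (!is.null(x$sim_power))
    cat(sprintf("\nSimulated power (%d reps): %.4f (minimax), %.4f (optimal)\n",
                p$sim_reps, x$sim_power["minimax"], x$sim_power["optimal"]))
  invisible(x)
}

#' @export
summary.surv2stage <- function(object, ...) {
  print(object)
  cat("\nBest design per n:\n")
  print(object$candidates, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.surv2stage <- function(x, ...) {
  cd <- x$candidates
  plot(cd$n, cd$ESS0, type = "b", pch = 16, xlab = "maximum sample size n",
       ylab = expression(ESS[0]), ...)
  points(x$minimax$n, x$minimax$ESS0, col = 2, pch = 17, cex = 1.4)
  points(x$optimal$n, x$optimal$ESS0, col = 4, pch = 15, cex = 1.4)
  legend("topright", legend = c("minimax", "optimal"), col = c(2, 4),
         pch = c(17, 15), bty = "n")
  invisible(x)
}
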