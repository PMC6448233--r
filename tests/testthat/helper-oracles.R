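# shared fixtures and independent oracles

panc_hyp <- function() surv_hypothesis(tc = 1, s0 = 0.35, s1 = 0.50)          # exponential
tab2_hyp <- function() surv_hypothesis(tc = 1, s0 = 0.50, hr = 0.5)           # exponential
k05_hyp  <- function() surv_hypothesis(tc = 1, s0 = 0.10, s1 = 0.25, shape = 0.5)

# closed-form exponential moment oracle (hazard rates h0, h1; requires t1 >= tc)
# I1(h) = int_0^tc t h exp(-h t) dt
exp_I1 <- function(h, tc) (1 - exp(-h * tc) * (1 + h * tc)) / h

exp_null_var <- function(h0, tc, t1) {
  stopifnot(t1 >= tc)
  list(s01sq = (1 - exp(-h0 * tc)) - exp_I1(h0, tc) / t1,
       s02sq = 1 - exp(-h0 * tc))
}

exp_alt_p <- function(h0, h1, tc) {
  list(p1 = 1 - exp(-h1 * tc),
       p0 = (h0 / h1) * (1 - exp(-h1 * tc)),
       p00 = h0^2 * exp_I1(h1, tc) / h1,
       p01 = h0 * exp_I1(h1, tc))
}

wu_var <- function(p) p$p1 - p$p1^2 - p$p0^2 + 2 * p$p0 * p$p1 + 2 * p$p00 - 2 * p$p01

# brute-force Simon oracle: enumerate every response/non-response sequence
simon_brute <- function(n1, r1, n, r, p) {
  n2 <- n - n1
  rej <- 0; pet <- 0
  for (bits in 0:(2^n - 1)) {
    seq_ <- as.integer(intToBits(bits)[1:n])
    prob <- prod(ifelse(seq_ == 1, p, 1 - p))
    x1 <- sum(seq_[1:n1])
    if (x1 <= r1) pet <- pet + prob
    else if (x1 + sum(seq_[n1 + seq_len(n2)]) > r) rej <- rej + prob
  }
  list(reject = rej, PET = pet)
}
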