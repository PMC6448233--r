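---
title: "Two-stage phase II designs with a survival endpoint under restricted follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage phase II designs with a survival endpoint under restricted follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(surv2stage)
```

## The design problem

Single-arm phase II trials with a time-to-event endpoint often ask a
landmark question: does the new treatment push survival through a
clinically meaningful follow-up time $t_c$ (say, one year) beyond what
historical controls achieve? Writing $S(t)$ for the survivor function of
the event time, the one-sided hypotheses are

$$H_0:\; S(t_c) \le S_0(t_c) \qquad \text{vs.} \qquad H_1:\; S(t_c) > S_0(t_c).$$

Event times are modelled as Weibull, $S(t) = \exp\{-(t/\lambda)^k\}$,
with the exponential as the special case $k = 1$. When the null and
alternative share the shape $k$, the hazard ratio
$\Delta = (\lambda_0/\lambda_1)^k$ is constant in time and is below 1
under the alternative of improved survival. Follow-up is *restricted*:
every patient is administratively censored at $t_c$, because only
survival through the landmark matters.

The trial has two stages, like a Simon design, but with an important
practical difference: enrolment never pauses. With accrual rate
$\theta$, the first $n_1$ patients are enrolled over $(0, t_1)$,
$t_1 = n_1/\theta$; a futility look happens at calendar time $t_1$ using
whatever follow-up those patients have accumulated; if the trial
continues, enrolment runs on to $n$ patients and the final analysis
happens at $n/\theta + t_c$, when everyone has completed follow-up.

## The one-sample log-rank test and its exact moments

Both looks use the one-sample log-rank statistic
$Z = (O - E)/\sqrt{E}$, where $O$ is the observed number of events and
$E = \sum_i \Lambda_0(O_i)$ accumulates the null cumulative hazard over
each patient's observed time. Small values favour the treatment.

The design calculus needs the first two moments of the normalised
statistics $W_1$ (interim) and $W$ (final). Administrative censoring
enters through the censoring survivor functions

$$G(t) = I(t \le t_c), \qquad
  G_1(t) = \max(0,\, 1 - t/t_1)\, I(t \le t_c),$$

the interim profile reflecting that a patient who entered at
$\tau \sim U(0, t_1)$ has only $t_1 - \tau$ of potential follow-up at
the look. Under the null, the variances are
$\sigma_{01}^2 = -\int_0^{t_c} G_1\, dS_0$ (interim) and
$\sigma_{02}^2 = 1 - S_0(t_c)$ (final), with correlation
$\rho_0 = \sigma_{01}/\sigma_{02}$. Under the alternative the means are
$E(W_1) = \sqrt{n_1}\,\omega_1$ and $E(W) = \sqrt{n}\,\omega$ with
$\omega = p_1 - p_0$ built from the integrals
$p_1 = \int G S_1\, d\Lambda_1$, $p_0 = \int G S_1\, d\Lambda_0$ (and
their $G_1$-weighted stage-1 versions), and the exact variances follow
Wu's formula
$\sigma^2 = p_1 - p_1^2 - p_0^2 + 2p_0p_1 + 2p_{00} - 2p_{01}$. All
integrals run by adaptive quadrature on $[0, t_c]$ (absolute tolerance
$10^{-12}$, split at the kink of $G_1$); for $k < 1$ the hazard has an
integrable singularity at zero which the adaptive rule handles. A
Monte-Carlo oracle (`mc_logrank_moments()`) that simulates the counting
processes directly is part of the package and validates every integral
in the test suite.

```{r}
hyp <- surv_hypothesis(tc = 1, s0 = 0.35, s1 = 0.50)
null_moments(hyp, t1 = 44 / 24)
```

Two reading notes on conventions, both of which matter when comparing
with other software. First, $W_1$ is treated as normalised by
$\sqrt{n_1}$, so that $E(W_1) = \sqrt{n_1}\,\omega_1$ and
$\mathrm{Var}(W_1) = \sigma_{01}^2$; the statistic
$Z_1 = (O-E)/\sqrt{E}$ is invariant to this choice. Second, the design
calculus uses $\rho_0 = \sigma_{01}/\sigma_{02}$ as the correlation of
the two statistics. Standard group-sequential theory would multiply by
the information fraction $\sqrt{n_1/n}$, and the Monte-Carlo oracle
confirms that the empirical correlation of $(W_1, W)$ is
$\rho_0\sqrt{n_1/n}$; we retain the $\sigma$-ratio form deliberately,
because it is what defines this design method and it reproduces the
published reference designs exactly. The practical consequence is that
the nominal error calculus is mildly conservative about the interim
look, which the simulation calibration below absorbs.

## Error rate, power, boundaries

The trial continues when $Z_1 < c_1$ and rejects when $Z \le c$.
Asymptotically $(Z_1, Z)$ is bivariate normal, so the type I error rate
is the bivariate normal CDF at $(c, c_1)$ with correlation $\rho_0$,

$$\mathrm{TIE} = \int_{-\infty}^{c} \phi(t)\,
  \Phi\!\left(\frac{c_1 - \rho_0 t}{\sqrt{1 - \rho_0^2}}\right) dt,$$

evaluated in closed form by a port of Genz's algorithm (`pbvnorm()`,
near machine accuracy; the defining quadrature is kept as an independent
cross-check via `type_one_error(..., method = "quadrature")`). Power is
the same integral with $\rho_1$ after shifting the boundaries to the
alternative scale,
$\tilde c_1 = (\sigma_{01}/\sigma_{11})(c_1 - \omega_1\sqrt{n_1}/\sigma_{01})$
and
$\tilde c = (\sigma_{02}/\sigma_{12})(c - \omega\sqrt{n}/\sigma_{02})$.
The final boundary transform is written here with the final-analysis
mean $\omega\sqrt{n}$; no other reading gives
$E(Z) = \sqrt{n}\,\omega/\sigma_{02}$, and this form reproduces the
published reference boundaries to all printed digits.

Given $c_1$ and $\rho_0$, the final boundary is the largest $c$ with
$\mathrm{TIE} \le \alpha$, found by bisection (the error rate is
strictly increasing in $c$; boundaries with $\Phi(c_1) \le \alpha$
cannot attain the level and are reported infeasible).

## The design search

`surv2stage()` scans total sample sizes $n$ upward. For each $n$, every
$n_1 \in \{1, \dots, n-1\}$ and every interim boundary on the grid
$c_1 \in \{-0.3, -0.295, \dots, 1.6\}$ (step 0.005, modifiable) is
paired with its solved final boundary; combinations reaching the
nominal power are candidates, and the candidate minimising the null
expected sample size

$$ESS_0 = n_1 + (1 - PET)(n - n_1), \qquad PET = 1 - \Phi(c_1),$$

wins at that $n$ (ties break toward smaller $n_1$, then smaller $c_1$,
making the scan fully deterministic). The *minimax* design sits at the
smallest feasible $n$; the *optimal* design minimises $ESS_0$; the scan
stops once $ESS_0(n)$ exceeds 110% of the running minimum. The expected
total study length under the null is
$ETSL_0 = t_1 + (1 - PET)(t_2 + t_c)$: a futility stop ends the study
at $t_1$ immediately, a continuing trial runs to $t_a + t_c$. These two
metric forms are fixed by requiring agreement with the published
reference designs at 0.1 precision; `PET` uses the asymptotic normal
law of $Z_1$. Moments depend on $(n_1, n)$ only through $t_1$, so they
are memoised per $n_1$ and a full search takes seconds.

```{r, eval = FALSE}
d <- surv2stage(hyp, accrual = 24, alpha = 0.10, power = 0.90,
                calibrate = FALSE)
d$minimax   # n1 = 42, n = 66 at the nominal level; see calibration below
```

## Simulation calibration of power

The bivariate normal law is an approximation, and in the sample-size
range of phase II trials it overstates power by one to a few percentage
points (the error-rate side is conservative and needs no correction).
`surv2stage(calibrate = TRUE)` therefore follows the asymptotic search
with a simulation check: both selected designs are simulated under the
alternative (100,000 trials each by default); if either falls short of
the nominal power, the search repeats with the nominal level raised by
one percentage point, until both simulated powers meet the original
nominal level. The number of raises is reported as `$adjustments`
(two raises, for instance, in the pancreatic example below). Because
the check is Monte Carlo at finite replicate counts, a design whose
true power sits within a fraction of a percent of the nominal level can
fall on either side of the decision in any single run; the seed makes
any particular run reproducible.

The simulator enrols stage-1 patients uniformly over $(0, t_1)$ and
stage-2 patients uniformly over $(t_1, t_a)$ — the process the $G_1$
profile describes, and the convention that matches the published
simulated operating characteristics of the reference designs. A variant
with a single pooled accrual stream over $(0, t_a)$ (under which the
interim's "first $n_1$ patients" can include late arrivals with no
follow-up, the literal reading of the observed-time formula
$O_i = \min(T_i, C_i, \max(0, t_1 - \tau_i))$) is available as
`simulate_oc(entry = "pooled")`; it yields interim information slightly
below the $G_1$ idealisation and correspondingly slightly lower power.
An interim with zero accumulated exposure ($E = 0$, possible at very
small $n_1 t_1$) is treated as "continue", which cannot inflate the
type I error rate. Boundary ties ($Z_1 = c_1$, $Z = c$) have measure
zero; the implementation stops on $Z_1 \ge c_1$ and rejects on
$Z \le c$.

## Worked example

The pancreatic-cancer setting — exponential survival,
$S_0(1) = 35\%$, $S_1(1) = 50\%$, $\alpha = 0.10$, power 90%,
accrual 24/year:

```{r, eval = FALSE}
d <- surv2stage(hyp, accrual = 24, alpha = 0.10, power = 0.90,
                sim_reps = 1e5, seed = 11)
d
#> Minimax design:  n1 = 44, n = 73, c1 = 0.240, c = -1.281
#>   PET = 0.4052, ESS0 = 61.3, ETSL0 = 3.15
#> Optimal design:  n1 = 41, n = 79, c1 = -0.085, c = -1.279
#>   PET = 0.5339, ESS0 = 58.7, ETSL0 = 2.91
```

The Simon binomial comparator for the same trial treats one-year
survival as a binary response:

```{r}
s <- simon2stage(0.35, 0.50, alpha = 0.10, power = 0.90, nmax = 110,
                 accrual = 24, tc = 1)
s$minimax
```

The survival design needs a slightly larger $ESS_0$ than Simon's
minimax (61.3 vs 59.3) but finishes far sooner ($ETSL_0$ 3.1 vs 4.0
years), because it never suspends accrual; against Simon's design *with*
interim accrual it wins on both counts.

## What the simulator does and does not emulate

The trial simulator generates exactly the data-generating process of
the design model: uniform accrual, independent Weibull event times,
administrative censoring at $t_c$, no other censoring. Passing
simulation checks therefore validates the moment integrals, the
bivariate-normal boundary calculus and the calibration loop — not the
robustness of the design to features the model excludes: patient
drop-out before $t_c$, non-uniform or seasonal accrual, delayed event
ascertainment, or mis-specification of the Weibull shape. In practice
the shape $k$ is the sensitive input: it is taken from historical data,
and a design computed under $k = 1$ can be noticeably over- or
under-sized when the true hazard is strongly decreasing ($k < 1$).

## Numerical choices

* Moment quadrature: adaptive, absolute tolerance $10^{-12}$, range
  split at $\min(t_1, t_c)$.
* Bivariate normal CDF: Genz's 6/12/20-point Gauss-Legendre scheme with
  the tail-stable branch for $|\rho| \ge 0.925$; validated against the
  defining integral at $10^{-9}$ in the tests.
* Boundary solve: bisection on $[-15, 10]$ to $10^{-9}$.
* Interim grid: $-0.3$ to $1.6$ by $0.005$, endpoints included;
  configurable.
* Search caps: $n$ starts at 5, safety cap 500; Simon search cap
  `nmax = 150` by default (all published settings fit well below).
* Replicate counts: 100,000 trials per calibration decision (the
  published procedure's count); the interval-reporting helper
  `replicate_interval()` defaults to 1000 batches of 10,000 but any
  budget can be set — the package's own tests use reduced sizes
  (20-40 thousand draws for module checks, up to $10^6$ where a
  knife-edge decision must be resolved decisively).
* Seeds: every simulating function takes a `seed`; `surv2stage()`
  derives per-check substreams from it, so a run is reproducible
  end-to-end.

## Known limitations

* Operating characteristics rest on the bivariate-normal limit; the
  calibration loop corrects its optimism in power but the error-rate
  statement is itself asymptotic (simulations show it held with slack
  in all settings examined by the test suite).
* The calibration's stopping decision is Monte Carlo; when a design's
  true power lies within ~0.1% of the nominal level, different seeds
  can stop one adjustment apart (the two adjacent answers differ by
  about one patient in $ESS_0$).
* Only administrative censoring is modelled; no drop-out.
* Two stages only, futility stopping only, and the null-optimality
  criterion ($ESS_0$); expected-duration-optimal designs are out of
  scope.
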