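# bsadose

Sequential dose finding for phase I clinical trials by Bayesian stochastic
approximation.

## The problem

A phase I trial searches an ordered set of candidate doses
`d_1 < ... < d_K` for the maximum tolerated dose (MTD): the dose whose
probability of dose-limiting toxicity (DLT) is closest to a target rate
`alpha` (typically 20–30%), with a total sample of around thirty patients.
Writing `pi(x)` for the (monotone increasing) DLT probability, the trial
estimates the quantile `theta = pi^{-1}(alpha)` sequentially, cohort by
cohort.

This package implements a design that models the dose–toxicity curve
*locally*: doses are scaled into `(0, 1]`, the unit interval is split into
`s` equal subintervals, and on the subinterval containing the current dose
the curve is approximated by a line through the target point,

    F(x) = alpha + beta (x - theta),        beta > 0,

with endpoint values `rho_0 = F(v_0) < rho_1 = F(v_1)` carrying the
noninformative order prior `2·1(0 < rho_0 < rho_1 < 1)` — no skeleton, no
hyperparameters. After every cohort, the posterior mean `E(theta | D_n)` is
computed from the observations inside the current subinterval, and the next
cohort is treated at the *neighbor* dose closest to it:

    a* = argmin { |d_a - E(theta | D_n)| : a = max(k-1,1), k, min(k+1,K) },

so dose skipping is impossible. Two frequentist quick actions accelerate
the search: escalation at every cohort until the very first DLT, and — once
`m_0 = 12` patients have accumulated at the current dose — a Wald-type 90%
logit interval around `logit(alpha)` that escalates, de-escalates, or
terminates the trial for toxicity when the lowest dose is already too
toxic. When the sample is exhausted, the recommended next dose under the
Bayesian rule is the MTD estimate. Historical information can be borrowed
by placing pseudo-observations at each dose (skeleton probabilities times a
prior effective sample size). A trial simulator reports the standard
operating characteristics (correct-selection rate, allocation at and above
the MTD, expected DLT count).

## A worked example

Six candidate doses with original levels −1.47 … 0.42 are scaled by
`(x + 1.5)/2`; the target rate is 20%. Suppose fast escalation has climbed
to the sixth dose and the first DLT appears in cohort 6:

```r
library(bsadose)
g <- dose_grid(c(-1.47, -1.1, -0.69, -0.42, 0, 0.42), alpha = 0.2, s = 3,
               mode = "linear", offset = -1.5, divisor = 2)
h <- data.frame(cohort = 1:6, dose_index = 1:6, n_patients = 3,
                n_dlt = c(0, 0, 0, 0, 0, 1))
summary(bsa(h, g))
```

```
Per-dose summary:
 dose scaled n dlt  phat phat_adj
    1  0.015 3   0 0.000    0.000
    2  0.200 3   0 0.000    0.000
    3  0.405 3   0 0.000    0.000
    4  0.540 3   0 0.000    0.000
    5  0.750 3   0 0.000    0.000
    6  0.960 3   1 0.333    0.333
Posterior mean of theta on the current subinterval: 0.7275
Decision: de-escalate -> dose 5  [bayes, E(theta|D) = 0.7275]
```

The local model on `(2/3, 1]` sees six observations (three toxicity-free at
0.75, one DLT among three at 0.96); its posterior mean 0.7275 is closest to
the fifth dose (0.75), so the design steps back down. Replaying the rest of
the example's outcomes produces the search path 1-2-3-4-5-6-5-5-5-5 and the
fifth dose as the MTD (`select_mtd(h, g)`).

Simulating the design against the classical tanh toxicity curve that
generated this example:

```r
scn <- tanh_scenario(g$original_levels, g)
operating_characteristics(simulate_trials(scn, reps = 200, seed = 2024))
```

```
Operating characteristics over 200 replicates:
  correct selection (PCS): 48.0%
  patients at MTD:         20.2%
  patients above MTD:      3.5%
  average DLT count:       3.18
  terminated for toxicity: 0.0%
```

Here the fifth dose (true DLT rate 0.24 against the 0.20 target) is
selected in about half the replicates of a 30-patient trial, with very few
patients treated above it — the overdose-control behaviour the local model
is designed for.

`predict(fit, depth = 3)` prints the decision tree for the next three
cohorts — every possible DLT count and the dose each branch leads to — so
the transitions can be tabulated before the trial and used without any
computation at the bedside.

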