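---
title: "A locally modelled Bayesian stochastic approximation design for dose finding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A locally modelled Bayesian stochastic approximation design for dose finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsadose)
```

## The problem

Phase I oncology trials search a small ordered set of candidate doses for the
maximum tolerated dose (MTD): the dose whose probability of a dose-limiting
toxicity (DLT) is closest to a prespecified target rate $\alpha$ (typically
20% or 30%). Writing $\pi(x)$ for the probability of DLT at dose $x$, assumed
strictly increasing, the trial is a sequential estimation of the quantile
$\theta = \pi^{-1}(\alpha)$ from a candidate set
$\mathcal{C} = \{d_1 < \dots < d_K\}$, with perhaps thirty patients in total.
Rule-based designs (3+3 and the interval designs) use only the rank of the
current dose; curve-based designs fit a global parametric model whose distant
data can distort a local quantile estimate. This package implements a middle
path in the stochastic-approximation tradition: a *local* linear model around
the current dose, updated by Bayes' rule, driving a one-step transition rule.

## The model

Doses are first mapped into $(0, 1]$ (see *Dose scaling* below) and the unit
interval is divided into $s$ equal subintervals $((j-1)/s,\; j/s]$. At any
point of the trial, the current dose $x_n$ lies in exactly one subinterval
$(v_0, v_1]$ with $v_0 = (\lceil x_n s\rceil - 1)/s$; the half-open
convention means a boundary dose belongs to the lower subinterval — this is
forced by the ceiling formula and is applied everywhere, including boundary
doses like $x = 1/3$ with $s = 3$.

On $(v_0, v_1]$ the toxicity curve is approximated by a line through the
target point $(\theta, \alpha)$:
$$F(x) = \alpha + \beta\,(x - \theta), \qquad \beta > 0 .$$
Writing $\rho_0 = F(v_0)$ and $\rho_1 = F(v_1)$ for the endpoint values, the
monotonicity of $\pi$ gives $0 < \rho_0 < \rho_1 < 1$, and the prior is the
noninformative order prior
$$p(\rho_0, \rho_1) = 2\,\mathbb{1}(0 < \rho_0 < \rho_1 < 1),$$
which encodes monotonicity and nothing else: no skeleton, no hyperparameters.
All observations whose scaled dose lies in the current subinterval enter the
Bernoulli likelihood through $F$, regardless of when they were collected.

The design treats the first cohort at $d_1$, then after every cohort computes
the posterior mean $E(\theta \mid \mathcal{D}_n)$ on the current subinterval
and moves to the *neighbor* dose closest to it:
$$a^\ast = \arg\min \left\{\, |d_a - E(\theta \mid \mathcal{D}_n)| :
  a = \max(k-1, 1),\, k,\, \min(k+1, K) \right\},$$
so dose skipping is impossible by construction. Ties are broken toward the
lower dose (a safety-first convention; the rule itself does not dictate
one). When the sample size is exhausted, the recommended next dose is the
MTD estimate.

## Computing the posterior of $\theta$

The slope is a nuisance. Given $\theta$, the admissible slopes form an
interval $(0, \beta_{\max}(\theta))$, where $\beta_{\max}$ is the steepest
line through $(\theta, \alpha)$ whose endpoint values stay inside $(0, 1)$;
the order prior induces the conditional density
$p(\beta \mid \theta) = 2\beta/\beta_{\max}^2(\theta)$ and the marginal
$p(\theta) \propto \beta_{\max}^2(\theta)$.

A subtlety decides the whole numerical design: under the unrestricted
push-forward of the order prior, the posterior of $\theta$ has tails of
order $1/\theta^2$ (as $\rho_1 - \rho_0 \to 0$ the crossing point runs off
to infinity while the likelihood stays bounded), so the posterior *mean*
does not exist without a support restriction. Doses live in $(0, 1]$, so the
package supports $\theta$ on the dose domain $(0, 1]$ — inside the current
subinterval the posterior is data-driven, outside it is damped by the
$\beta_{\max}^2$ prior factor. Restricting $\theta$ to the current
subinterval alone was considered and rejected: it concentrates the posterior
too strongly and changes the transition behaviour materially (the
de-escalation after a first DLT at a high dose becomes much weaker).

Two numerical schemes are provided by `local_posterior()`:

* **`method = "sequential"`** (default, and the scheme driving all
  decisions): the $\theta$-marginal is updated one observation at a time;
  for each observation the slope is integrated against its conditional
  prior, giving the predictive rate
  $\tilde F(x \mid \theta) = \alpha + \tfrac{2}{3}\beta_{\max}(\theta)\,(x - \theta)$
  (clipped to $[0,1]$), and
  $h(\theta) \propto \beta_{\max}^2(\theta) \prod_i \tilde F(x_i\mid\theta)^{y_i}
  \,(1 - \tilde F(x_i\mid\theta))^{1-y_i}.$
  The factors commute, so the result does not depend on the order in which
  observations arrived — consistent with the data-eligibility rule above.
  Each factor is non-increasing in $\theta$ for a DLT and non-decreasing for
  a non-DLT, which yields the likelihood-ratio monotonicity the tests
  verify: appending a non-DLT strictly raises the posterior mean, a DLT
  strictly lowers it.

* **`method = "joint"`**: direct numerical integration of the joint
  posterior of $(\beta, \theta)$ — equivalently of $(\rho_0, \rho_1)$ over
  the order triangle — with the slope integral done by a midpoint rule at
  each $\theta$ grid point. This is the fully Bayesian marginal; it is kept
  as the reference for the Monte-Carlo-oracle and
  reparameterization-consistency tests (a $10^6$-draw importance sampler
  over the triangle agrees with it to within three standard errors).

The two schemes differ: the sequential recursion refreshes the conditional
slope prior at each observation instead of propagating slope–quantile
dependence. It is the scheme whose posterior-mean trace on the package's
worked six-dose example (target 20%, first DLT on patient 18) tracks the
behaviour expected of the design — rising after toxicity-free cohorts,
dipping after a DLT — and it is several times cheaper, which matters in
simulation. Both schemes return the density on a $\theta$ grid (default
`resolution = 400` midpoints of $(0,1]$; below 32 an error is raised),
normalized so the trapezoid integral is 1; the reported mean is the
trapezoid mean of that density, so density and mean are self-consistent by
construction. Degenerate likelihood cells ($F$ exactly 0 or 1 against a
contradictory outcome) receive zero posterior weight rather than raising
errors, and an empty data set returns the prior push-forward through the
same code path — no special-cased constant.

## Quick actions and coherence

Two frequentist shortcuts bypass the Bayesian step, in this order:

1. **Fast escalation.** Until the very first DLT anywhere, each cohort
   escalates one level (when a next level exists; at the top dose the
   Bayesian step takes over).
2. **Wald interval.** Once $m_k \ge m_0$ patients (default 12) have
   accumulated at the current dose, the observed DLT frequency
   $\hat p_k$ — monotonicity-adjusted by the two-point
   pool-adjacent-violators rule, which replaces a violating adjacent pair by
   its average — is compared with the interval obtained by inverting
   $\mathrm{logit}(\hat p_k) \approx N(\mathrm{logit}(p_k),
   \{m_k p_k (1-p_k)\}^{-1})$ at $p_k = \alpha$:
   $c_{1,2} = \mathrm{logit}(\alpha) \mp z_\xi\,\{m_k\,\alpha(1-\alpha)\}^{-1/2}$
   mapped through the inverse logit (default $\xi = 0.05$, a 90% interval).
   Below the interval: escalate; above: de-escalate, or *terminate the
   trial for toxicity* when the current dose is the lowest. The check uses
   the current dose only.

The design is advertised as *coherent*: a cohort that is all DLTs must never
trigger escalation, and a toxicity-free cohort must never trigger
de-escalation. For a memoryless neighborhood rule this does not come for
free — with sparse data the prior-dominated posterior mean can sit below the
current dose even after a clean cohort (most visibly right after the dose
changes subinterval, where the eligible data set changes discontinuously),
and the Wald action responds to cumulative rather than latest evidence. The
package therefore *enforces* coherence as part of the policy: when an
all-DLT cohort would escalate or an all-non-DLT cohort would de-escalate,
the decision is capped at "stay". Mixed cohorts are unrestricted, and
toxicity termination — a safety stop on cumulative evidence — is never
capped. The cap provably never fires on the package's worked example, and
an exhaustive enumeration of all single-patient-cohort outcome sequences
(in the test suite) confirms zero incoherent decisions.

**MTD selection.** The final recommendation applies the Bayesian
neighborhood rule to the complete data. The quick actions are deliberately
excluded here: they exist to accelerate the search, and the Wald escalate in
particular can fire on the final state of a well-behaved trial (a dose with
one DLT in fifteen patients sits below the lower bound) and would push the
recommendation above the dose the posterior supports. A trial that ends
without any DLT is prior-dominated, and the recommendation is the
fast-escalation continuation $\min(k+1, K)$. A toxicity-terminated trial
returns no MTD.

## Dose scaling

`auto_scale()` chooses between the raw and the natural-log scale by spacing
regularity — the coefficient of variation of successive differences —
selecting the scale on which the levels are closer to equally spaced
(additive spacing keeps the raw scale, multiplicative spacing such as
100, 200, 400, 800 selects the log scale). The affine map then leaves a
half-step margin at each end: $\delta = (\max - \min)/(2(K-1))$,
$x \mapsto (x - \min + \delta)/(\max - \min + 2\delta)$, which for the
levels $1,\dots,5$ gives exactly $(x - 0.5)/5$, i.e. scaled doses
$0.1, 0.3, \dots, 0.9$. Explicit `offset`/`divisor` always override the
automatic rule. Scaled values are kept at full precision; any output
outside $(0, 1]$ is an error naming the offending level.

## Historical information

With an elicited skeleton $q_1 < \dots < q_K$ and per-dose prior effective
sample sizes $n_{0k}$, `build_pseudo_data()` forms $a_k$ DLT and $b_k$
non-DLT pseudo-observations at dose $d_k$ — the nearest integers to
$n_{0k} q_k$ and $n_{0k}(1 - q_k)$ (half-up rounding; $a_k + b_k$ may miss
$n_{0k}$ by one, which the nearest-integer rule accepts). Pseudo-observations
enter the local likelihood exactly like real patients, but only the Bayesian
step sees them: the quick actions and the observed frequencies $\hat p_k$
use real data only, so borrowing cannot trigger a Wald move by itself. With
all $n_{0k} = 0$ the design is identical to the no-borrowing design (a test
asserts decision-level identity). For a vague prior, `pess_default()`
returns an integer in $[N/(3K),\, N/(2K)]$ — the largest by default, e.g. 3
for $N = 30, K = 5$ and 2 for $K = 6$.

## The simulator and its scenario generators

`run_trial()` draws per-patient Bernoulli outcomes from a scenario's true
toxicity vector, applies the policy after every cohort, and stops at the
maximum sample size (default 30, cohorts of three; single-patient,
two-patient, schedules, and random-in-$\{1,2,3\}$ cohorts are supported —
the policy is evaluated after every completed cohort whatever its size) or
on termination. Each replicate uses one random stream seeded by root seed
plus replicate index, so replicate sets are reproducible and could be
distributed. `operating_characteristics()` reports the four standard
metrics: the percentage of replicates selecting the true MTD (PCS), mean
percentage of patients at the MTD, mean percentage treated above it, and
the mean DLT count. Terminated replicates count as incorrect selections and
keep their enrolled patients in the allocation denominators (the metrics
flag the termination rate so other conventions can be tabulated).

Scenario sources:

* `tanh_scenario()` — the smooth curve
  $\Pr(y=1) = \{(\tanh x + 1)/2\}^2$ at the original dose values, the
  classical six-dose illustration.
* `random_scenario()` — draws the MTD's toxicity uniformly within 0.05 of
  the target, the gaps to its neighbors uniformly from $(0.05, 0.3)$, and
  extends outward with increasing uniform increments, rejecting draws whose
  implied MTD shifts. This is a documented approximation of the
  pseudo-uniform construction used in comparative studies of interval
  designs — the original algorithm is not reproduced here, so averages over
  these scenarios are tolerance-checked, not matched digit by digit.
* `random_exact_doses()` — places the scaled MTD dose at 0.3/0.5/0.7
  (early/middle/late) with the other doses drawn outside a $\pm 0.05$
  vicinity, for studying the value of exact dose information.

What the generators do *not* emulate: patient heterogeneity, late-onset or
graded toxicity, accrual gaps, and deviations from monotonicity. Passing
simulations therefore say nothing about those features of real trials; they
validate the decision logic and the estimator under the idealized binary
monotone model.

## Tuning parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | — | target DLT probability, in $(0,1)$ |
| `s` | 3 | subintervals of $(0,1]$; 3–4 recommended for $K \le 6$, 5 for $K \ge 7$ (smaller $s$ = wider locality = more conservative moves; `dose_grid()` warns when $s > 4$ with $K \le 6$) |
| `m0` | 12 | patients at one dose before the Wald action may fire |
| `xi` | 0.05 | Wald tail probability (90% interval) |
| `max_n` | 30 | maximum sample size |
| `cohort_size` | 3 | integer, schedule, or `"random"` ($\{1,2,3\}$) |
| `resolution` | 400 | $\theta$ grid points (and slope points for `"joint"`) |
| `wald` | TRUE | disable to run with fast escalation as the only quick action |

## Problem sizes used by the test suite

The stochastic checks are sized for a desk run: the long-horizon allocation
check uses 100 single-patient-cohort trials of 300 patients at a reduced
posterior grid (64 points — transition decisions need far less resolution
than 3-decimal estimation), the random-scenario accuracy check uses 100
scenarios with five replicates each (500 trials), and the exhaustive
coherence enumeration covers all outcome sequences of five to six
single-patient cohorts. The Monte-Carlo oracle uses $10^6$ draws.

## Known limitations

* The sequential recursion is an approximation to the fully Bayesian
  marginal; the two agree qualitatively but not to three decimals, and the
  package standardizes on the sequential scheme for decisions.
* Monotone toxicity is assumed throughout; the design is not suitable for
  optimal-biological-dose questions where activity plateaus.
* Drug combinations, covariates, and time-to-toxicity outcomes are out of
  scope.
* The random-scenario generator is an approximation (see above); its
  operating characteristics carry generator as well as Monte-Carlo
  uncertainty.
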