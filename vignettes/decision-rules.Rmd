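---
title: "Comparing one-trial, two-trial and random-effects decision rules for pivotal trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing one-trial, two-trial and random-effects decision rules for pivotal trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pivotalOC)
```

## The decision problem

A sponsor must demonstrate a drug's effectiveness to a regulator. The
conventional requirement is two pivotal trials, each significant one-sided
at $\alpha/2 = 0.025$; the pooled alternative is a single analysis of the
combined data at one-sided level $(\alpha/2)^2 = 0.000625$, calibrated so
that the two procedures have the same type I error when both true
treatment differences are exactly zero. These are genuinely different
tests of genuinely different hypotheses, and this package computes, for
any design and effect configuration, exactly what each rule's error rate
and power are.

## Model and assumptions

$N$ patients are split between two trials ($N_1 = fN$, $N_2 = (1-f)N$,
$0 < f < 1$ fixed in advance), randomized 1:1 within trial, so each arm
has $n_1 = fN/2$ or $n_2 = (1-f)N/2$ patients. Outcomes are independent
normal with **known** common variance $\sigma^2$ (default 1, making
treatment differences Cohen's $d$ values); only z-tests are offered —
estimated-variance t-statistics are deliberately out of scope, matching
the known-variance model throughout. The true treatment differences are
$\Delta_1$ and $\Delta_2$; the pooled analysis targets the average effect
$\tilde\Delta = f\Delta_1 + (1-f)\Delta_2$.

The per-trial statistics $Z_1, Z_2$ and the pooled
$Z = \sqrt{f}Z_1 + \sqrt{1-f}Z_2$ (the inverse normal combination; the
squared weights sum to 1, so $Z$ is standard normal at the null) are
jointly normal with unit variances,
$\mathrm{corr}(Z_1, Z_2) = 0$, $\mathrm{corr}(Z_1, Z) = \sqrt{f}$, and
means

$$\delta_1 = \Delta_1\sqrt{fN/4\sigma^2},\qquad
  \delta_2 = \Delta_2\sqrt{(1-f)N/4\sigma^2},\qquad
  \delta = \tilde\Delta\sqrt{N/4\sigma^2},$$

linked by the exact identity
$\delta = \sqrt{f}\,\delta_1 + \sqrt{1-f}\,\delta_2$ (a property test
asserts it over a randomized grid).

### The two null frames

The two-trial rule rejects when both $Z_k > \Phi^{-1}(1-\alpha/2)$; it is
a union–intersection test of $H_0 = H_0^1 \cup H_0^2$ (at least one
$\Delta_k \le 0$). The one-trial rule rejects when
$Z > \Phi^{-1}(1-(\alpha/2)^2)$ and tests $\tilde\Delta \le 0$. The frames
coincide only on the diagonal $\Delta_1 = \Delta_2$: a scenario such as
$(\Delta_1, \Delta_2) = (-0.5, 0.8)$ with $f = 0.5$ is *null* for the
union frame but *alternative* for the average frame, and no amount of
calibration can reconcile the rules there. `classify_scenario()` labels
scenarios under either frame; a scenario exactly on a boundary is labelled
`"boundary"` and counted with the null, the usual convention for one-sided
error accounting.

### Closed forms and their extremes

```{r}
cfg <- trial_config(total_n = 500, fraction_f = 0.5)
oc_grid(cfg, 0, 0)[, c("p_two", "p_one")]
```

Independence of the trials gives
$p_{two} = \bar\Phi(c_{two}-\delta_1)\,\bar\Phi(c_{two}-\delta_2)$ and
normality of the pooled statistic gives
$p_{one} = \bar\Phi(c_{one}-\delta)$. Over the union null the worst cases
sit on the boundary where one difference is zero and the other grows:
the zero-effect trial still rejects with probability $\alpha/2$, so
$p_{two} \uparrow \alpha/2$, while the pooled statistic is dragged across
its threshold and $p_{one} \uparrow 1$. `boundary_sup()` returns these
analytic limits rather than numerically maximizing — the limits are exact,
and a grid sweep in the test suite (noncentralities up to $\pm 8$, and to
$20$ for the slowly saturating one-trial case) confirms the closed forms
approach them monotonically from below. Rejection is strict
($Z > c$, not $\ge$): a measure-zero choice invisible to simulation, fixed
for determinism.

## The random-effects rule

Framing the two populations as draws from a distribution of populations,
$\hat\Delta_k \sim N(\Delta_k, s_k^2)$ with
$\Delta_k \sim N(\Delta, \tau^2)$ and known $s_k^2 = 2\sigma^2/n_k$, leads
to the meta-analytic statistic
$Z_{RE} = \hat\Delta\sqrt{\textstyle\sum_k w_k}$ with
$w_k = 1/(s_k^2+\tau^2)$, tested against $\Phi^{-1}(1-(\alpha/2)^2)$. With
$\tau^2 = 0$ the weights are proportional to the sample sizes and
$Z_{RE}$ **is** the pooled one-trial statistic, exactly (an algebraic
identity, asserted to $10^{-10}$ on simulated datasets).

$\tau^2$ is estimated by the DerSimonian–Laird moment estimator (the
default for all headline outputs), truncated at zero:
$\hat\tau^2 = \max\{0, (Q - (K-1)) / (\sum v_k - \sum v_k^2/\sum v_k)\}$
with fixed-effect weights $v_k = 1/s_k^2$ and Cochran's $Q$. ML and REML
alternatives use a fixed-point iteration (tolerance $10^{-8}$,
at most 200 iterations, truncation at zero each step); all three are
cross-checked against an independent meta-analysis implementation in the
test suite. The uncertainty of $\hat\tau^2$ — severe with $K = 2$ — is
deliberately ignored in the test, as is standard practice;
Hartung–Knapp-type corrections are not offered, which is precisely why the
estimated-$\tau^2$ rule fails to hold its level under heterogeneity (see
below).

## Simulation design

Two simulation engines back every closed form:

* `generate_trial_data()` draws patient-level outcomes (control means
  fixed at 0 — only differences enter any formula, so absolute means are
  not identifiable and a location shift changes nothing) and
  `z_statistics()` computes the statistics **twice**, from pooled sums and
  as the weighted combination, asserting agreement.
* `monte_carlo_oc()` by default draws the z statistics from their exact
  sampling distribution: under known $\sigma^2$ the arm means are
  sufficient, so the summary draw is *distributionally identical* to the
  patient-level path, not an approximation. `mode = "patient"` runs the
  full per-patient path and the test suite verifies the two modes agree
  with the closed forms within Monte Carlo error. The same sufficiency
  argument lets `simulate_re_oc()` operate at the summary level
  ($\hat\Delta_k$ given $\Delta_k$).

Arm sizes are rounded (`round(fN/2)`); the *effective* fraction
$n_1/(n_1+n_2)$ implied by the rounded sizes is used in the combination
weight so the pooled-statistic identity stays exact rather than holding
only approximately.

Reproducibility: every stochastic function takes an explicit seed.
`simulate_re_oc()` draws the between-trial innovations before the
within-trial ones, so runs at different $\tau^2$ under one seed share
common random numbers — the device behind the monotonicity comparisons
(type I error non-decreasing in $\tau^2$), which would otherwise need far
more replicates to resolve.

```{r}
rates <- vapply(c(0, 0.01, 0.25, 1), function(t2) {
  simulate_re_oc(trial_config(500, 0.5), heterogeneity_scenario(0, t2),
                 estimator = "dl", n_reps = 2e4, seed = 9)$reject_rate
}, numeric(1))
round(rates, 4)   # nominal level is 0.000625 at tau^2 = 0
```

When $\tau^2$ is instead **known** and the per-trial effects are drawn
around fixed means with that heterogeneity, the rejection probability has
the closed form implemented in `p_re_known()`,
$\bar\Phi(c_{one} - \sum_k w_k\Delta_k/\sqrt{\sum_k w_k})$: at
$\Delta_1 \le 0, \Delta_2 = 0$ it exceeds both classical rules already at
$\tau^2 = 0.1^2$ yet never exceeds $(\alpha/2)^2$ — heterogeneity
acknowledged in the weights shrinks a negative trial's influence without
breaking the level, whereas heterogeneity *estimated* from two trials
does break it. This generative reading (effects drawn around the stated
means) is the only one consistent with both directional facts; under
fixed effects with $\tau^2$ merely plugged into the weights, the
rejection probability would *decrease* in $\tau^2$.

## Defaults and parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `level_a` | 0.025 | per-trial one-sided level; the conventional two-sided 0.05 |
| `sigma2` | 1 | known outcome variance; effects are then Cohen's $d$ |
| `total_n` (CLI, figures) | 500 | a typical phase III total; absolute curve heights scale with $N$, every qualitative comparison is $N$-free |
| grid ranges (CLI) | $\Delta \in [-1, 1]$, step 0.05 | covers small-to-large standardized effects |
| `n_reps` | $10^5$ | resolves probabilities of order $10^{-3}$ with relative SE $\approx$ 10% |
| $\tau^2$ grid | $\{0, 0.1^2, 0.5^2, 1\}$ | none-to-severe heterogeneity on the $d$ scale |

The test suite and the acceptance sweep use these sizes ($10^5$
replicates for stochastic checks, $2\times10^5$ where the target
probability is $6.25\times10^{-4}$; tolerance four binomial standard
errors), chosen so each stochastic assertion has comfortable power while
the whole suite stays quick to run.

## What the synthetic data do and do not show

The generator reproduces the model faithfully: independent normal
outcomes, known common variance, fixed per-population patient counts,
1:1 randomization, parallel (non-sequential) trials. Passing tests
therefore validate the mathematics of the decision rules *under the
model*. They say nothing about unknown or unequal variances, binary or
survival endpoints, dropout, covariate imbalance, interim looks, unequal
randomization, more than two trials, or the one-trial design in which
patients are drawn from a population mixture at random (random, rather
than fixed, per-population counts) — all outside the model by design.
Sample-size planning for a target power is likewise out of scope.

## Numerical choices and degenerate inputs

* Probabilities come from `pnorm`/`qnorm`; no hand-rolled distributions.
* `trial_config` requires $N \ge 4$, $f \in (0,1)$ open, $\sigma^2 > 0$,
  `level_a` $\in (0, 0.5)$; patient-level simulation additionally requires
  each rounded arm to hold at least one patient and fails loudly
  otherwise.
* The DL estimator needs $K \ge 2$ studies; with identical estimates it
  returns exactly 0 (truncation), never a negative variance.
* Ties at a rejection threshold do not reject (strict inequality).
* CLI exit codes: 0 success, 2 invalid input, with the violated constraint
  named on stderr; numeric output goes only to files/stdout so pipelines
  stay clean.

## Known limitations

The framework inherits the known-variance idealization: real pivotal
trials estimate $\sigma^2$, and at phase III sizes the z/t distinction is
negligible but not zero. The random-effects rule with $K = 2$ rests on a
one-degree-of-freedom estimate of $\tau^2$; its simulated operating
characteristics quantify, rather than repair, that fragility. Absolute
rejection-probability curves depend on $N$, which figure-style outputs
expose as an explicit option.
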