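---
title: "Chi-square tests for interval-valued counts: model, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chi-square tests for interval-valued counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrochisq)
```

## The model

A count recorded under indeterminacy is an interval [N_L, N_U]: N_L is
the exact (determinate) part, N_U bounds the indeterminate part. The
null hypothesis is that all K counts share one expected value; under a
Poisson-type recording model the dispersion statistic
sum (N_i − Nbar)² / Nbar is referred to a central chi-square
distribution. `neutrochisq` evaluates every quantity **component-wise**
— all lower endpoints give one number, all upper endpoints the other —
so a derived result is an indexed pair, not an interval in the
arithmetic sense. This mirrors how the method is defined; no general
interval arithmetic is performed, and a derived pair carries no ordering
(for the bundled pulse data the statistic is [146.97, 121.79]: the wider
upper counts sit relatively closer to their larger mean).

For unequal observation times t_i the pooled rate Rbar = ΣN/Σt replaces
the mean, expected counts are t_i·Rbar, and with all times equal the
statistic reduces algebraically to the equal-time one — a reduction the
test suite checks to 1e-9 relative on randomized data.

## The neutrosophic form and its indeterminacy measure

A pair (l, u) is rewritten as a + b·I with a = l, |b| = |u| and
I ∈ [0, I_U]. The measure

I_U = |u − l| / |u|

is the relative gap between the components. It is not given as a closed
formula in the literature this package follows; we inferred it from the
two published worked decompositions (mean form 73.54 + 91.8·I with
I_U = 0.1989; statistic form 146.97 − 121.78·I with I_U = 0.2068), both
of which it reproduces, and flag it as an inference. The coefficient
carries a sign chosen so the form interpolates from l (at I = 0) to u
(at I = I_U); this is what makes both published signs come out. I_L is
always 0: the determinate end of the form is exact. Crisp pairs give
I_U = 0, and I_U is invariant under positive rescaling of both
components. A pair with u = 0 and l ≠ 0 has no well-defined measure and
is rejected; the all-zero pair collapses to 0 + 0·I.

## Decision conventions

Several choices here were genuinely open and are fixed as follows.

* **Degrees of freedom.** The reference distribution defaults to df = K,
  which is the convention the published worked example uses (its
  critical values 34.76 and 67.50 are the 5 % and 95 % chi-square
  quantiles at df = 50). The classical dispersion-test convention
  df = K − 1 (one degree lost to the estimated mean) is available via
  `df_rule = "K-1"`.
* **Two-sided region.** The test rejects below the α-quantile and above
  the (1−α)-quantile, so α is a *per-tail* mass, matching the pairing of
  α = 5 % with those two quantiles. Note this also rejects
  *under*-dispersed data: perfectly constant counts give a statistic of
  0, below the lower critical value, and are flagged as too regular for
  the Poisson-type null.
* **Tri-state decision.** Both components strictly outside the region
  reject; both inside (boundary values count as inside) retain; one in,
  one out returns `"indeterminate"` — with interval data a straddling
  statistic supports neither verdict, and making that explicit is the
  point of the approach.
* **Precision.** All arithmetic runs in full double precision; rounding
  (2 dp for per-count terms and statistic endpoints, 4 dp for sums and
  I_U) happens only in reports.

## The simulator and the rejection-rate study

`generate_interval_counts()` draws integer endpoints uniformly on
[low, high], by default [45, 55] with K = 50 — the conditions of the
published Monte-Carlo study, whose generation law is stated only as
"from 45 to 55". Two endpoint constructions are offered: sort two
uniform draws (default), or draw a lower endpoint plus a uniform width.
Integer uniform draws are the least-assumption reading of that
description; K = 50 matches the worked example.

`estimate_rejection_rate()` reports, per component, the fraction of
simulated datasets whose statistic falls in the rejection region. The
neutral name is deliberate: the source study labels this quantity power
(1 − β) while defining β as the probability of rejecting a true null,
which is a type-I error rate; rather than guess which was tabulated, the
package reports the rejection proportion and lets the user supply data
generated under whichever hypothesis they intend. For the same reason
the published power table is not a numerical reproduction target here.
Printed significance levels above 0.5 (0.92, 0.94, …) cannot feed an
α/(1−α) quantile rule and are interpreted as 1 − α.

`power_curve()` scores every level in the grid against the *same*
simulated datasets, drawn sequentially from one seeded stream (common
random numbers). Consequences: a one-level grid equals the single-level
estimate exactly, curves are exactly monotone in α (a wider rejection
region can only gain hits), and runs are bit-reproducible for a fixed
seed. Under the two-sided convention, larger α widens the rejection
region, so rejection rates rise with α — the direction the published
study also observes. Default study sizes in the test suite (up to 2000
replications of K = 50 counts) give Monte-Carlo standard errors below
0.012 and run in seconds.

What the simulator does *not* emulate: real pulse-count series are
overdispersed across patients (the worked data reject the null
decisively), have interval widths that grow with the count, and are not
bounded in a ±5 window. Passing property tests on uniform [45, 55] data
therefore validate the machinery (calibration direction, determinism,
component bracketing), not any clinical claim.

## Degenerate inputs and numerical notes

Empty tables, single counts (K < 2), negative endpoints, inverted
intervals, nonpositive times, and all-zero components are rejected with
messages naming the offending row. Chi-square quantiles come from
`stats::qchisq`; the test suite cross-checks them against an independent
bisection on the regularized lower incomplete gamma to 1e-6. The
statistic's component-wise summation is checked against naive
per-element loops, and on crisp data against the classical statistic, to
1e-9 relative.

## Known limitations

* The indeterminacy measure is an inference from two worked
  decompositions, not a published formula.
* The tri-state rule treats the pair as a unit; users wanting a
  "reject if any component rejects" rule must inspect the components
  themselves.
* Contingency-table chi-square tests, goodness-of-fit against arbitrary
  expected distributions, and continuity corrections are out of scope.
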