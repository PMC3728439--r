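---
title: "Lead-time TTO valuation: model, simulator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lead-time TTO valuation: model, simulator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadtto)
```

## The valuation model

Lead-time TTO values a health state by a single uniform procedure for
states better and worse than dead. Life A lasts `LT + UT` years: `LT` years
of full health (the lead time) followed by `UT` years in the state under
valuation. Life B is `x` years of full health. The indifference duration
`T` maps to the state's value

$$U = \frac{T - LT}{UT}, \qquad U \in \left[-\frac{LT}{UT},\, 1\right].$$

`T = LT` means the respondent traded away exactly the lead time, so the
state is equivalent to dead (`U = 0`); `T < LT` gives negative values; and
`T = 0` pins the floor `−LT/UT` — `−2` in the 10 + 5 design, `−1` in the
5 + 5 design. Values below the floor are not observable: the tradable time
is exhausted and the record is censored.

All durations live on a 3-month grid (`0.25` years), the finest step of the
iterative procedure; internally they are integer quarter-year counts, so
bracket arithmetic is exact and value comparisons need no floating-point
tolerance beyond round-off of a single division. The value resolution of a
design is `min_step / UT` (`detectable_resolution()`): 0.025 with a 3-month
step over 10 unhealthy years, only 0.05 over 5 years — the measurement
argument for longer unhealthy periods.

## The iterative search

`run_task()` implements the offer sequence as a bracketing search:

1. Offer 1 is `LT + UT` (Life B at value 1). Preferring Life A here settles
   the task at the ceiling.
2. Offer 2 is `LT` (value 0, the point equivalent to dead).
3. Every later offer is the integer-quarter midpoint of the current
   preference bracket — after "B at `LT + UT`, A at `LT`" the third offer
   is the midpoint of `(LT, LT + UT)` (12.5 years in the 10 + 5 design);
   after "B at `LT`" the search moves to `LT/2` (5 years, i.e. value −1;
   2.5 years in the 5 + 5 design, value −0.5).

Each response moves one bracket endpoint to the offer just posed. Because
every offer lies strictly inside the bracket, the bracket shrinks at every
step even under inconsistent (noisy) answers, and the search terminates in
at most ~10 questions; a defensive cap of 64 guards the agent contract.
When no unoffered grid point remains inside the bracket, the respondent is
asked to settle at the closer bracket endpoint — the record is flagged
`censored`, covering both genuine exhaustion at the grid bounds and an
interior indifference point finer than the grid can express. For an
error-free agent whose utility lies on the value grid the procedure is
exact: the elicited value equals the utility, verified exhaustively over
both arm grids in the test suite.

The published account of the procedure fixes only the first three offers
and the 3-month-to-1-year step range; the continuation is specified in an
instrument manual that is not restated there. The quarter-grid bisection
used here is therefore a documented stand-in: it reproduces all printed
anchor offers, stays within the stated step range at every depth, and
reaches quarter-year resolution within the question counts the published
behaviour tables report (4–9 per task). Likewise the garbled printed third
offer "12.5 (respondent 5)" is read as "12.5 (resp. 5)": 12.5 after Life A
at the second question, 5 after Life B — the only reading symmetric with
the 5-year variant's printed "2.5 (7.5)". The engine forbids revising
earlier answers; whether the fielded instrument allowed it is unstated.

## The synthetic respondent

An agent holds latent per-state utilities `u*` and acts on an *effective*
utility under a task design:

$$u_{\mathrm{eff}} = u^* - \kappa\left(\frac{LT}{UT} - 1\right)
  - \nu\,\frac{LT + UT - 10}{10}.$$

* `decision_sd` (σ, default 0.15): SD of zero-mean noise ε added to the
  perceived value of each offer. The agent reports indifference when
  `|v − u_eff + ε| ≤ δ`, otherwise prefers Life B exactly when the
  perturbed offer value exceeds `u_eff`.
* `indifference_tol` (δ, default 0.05): half-width of the "about the same"
  band — one grid step of the 10 + 5 design, so an error-free agent stops
  at the first grid point within half a step of its utility.
* `framing_coeff` (κ): extra trading per unit excess of the `LT/UT` ratio
  over 1 — people trade more time when more is available.
* `visual_error_coeff` (ν): downward bias growing with total bar length
  beyond 10 years — longer bars make the length contrast at indifference
  less striking, so respondents trade a little more to sense it.
* `engagement_gain` (γ): raised-bar variant only. When a *refinement* offer
  (ordinal ≥ 3) has `|v| < 0.5`, the highlighted dead-point prompts more
  deliberation: the indifference band shrinks to `δ/(1+γ)` and the
  per-question time inflates by `1+γ`.
* `base_log_time`, `time_sd`: per-question time is lognormal
  (default `exp(N(log 5.5, 0.35))` seconds, giving task durations around
  half a minute at typical question counts).

Both κ and ν are normalized to vanish in the 5 + 5, 10-year-bar design, so
they are identified as contrasts against that arm. The linear forms are
this package's choice; the mechanisms they encode are qualitative in the
source literature.

The engagement effect deliberately excludes the two fixed opening offers
and the boundary value 0.5. The openers (values 1 and 0) are posed in
*every* task, and the first midpoint after a positive bracket is always
value 0.5; inflating them would raise every task's duration in the raised
-bar arm roughly uniformly, which contradicts the published localization of
the effect — longer times only for tasks that *end* near 0. Restricting the
effect to refinement offers strictly inside `(−0.5, 0.5)` concentrates the
extra time in tasks whose search actually dwells near the dead point, and
the simulated behaviour table then reproduces the published pattern:
strongly significant time differences in the `(0, 0.5]` and `[−0.5, 0)`
bins, none in the outer bins.

`sample_population()` draws per-state utilities from normal distributions
truncated to `[−2, 1]` (inverse-CDF, so no boundary atoms), balanced
randomized arm assignment, random block assignment, and demographics from
stated category frequencies. The shipped default state means (0.2–0.6,
between-respondent SD 0.5) are illustrative — chosen to give a value
distribution with its mode in the upper half and secondary mass at the
bounds — not fitted to any data set, since the underlying respondent-level
data are not public.

### What the simulator does and does not emulate

It reproduces the study *structure*: two arms, two fixed 5-state blocks,
respondent-level clustering, censoring at the grid bounds, question counts
and time stamps, and the three bias mechanisms. It does not emulate
learning or fatigue across the five tasks, cultural or demographic effects
on utilities (demographics act only as analysis covariates), shortcut
behaviour such as random instant indifference, or time preference (the
source study did not adjust for it either). Passing tests on simulated data
therefore validate the procedure, the filters and the statistical
machinery — not any substantive claim about real populations.

A known operating characteristic: under decision noise the staircase has a
small downward bias (about −0.01 on the value scale at σ = 0.15), because
early noisy stops occur disproportionately at the heavily-visited low
anchor offers and the ceiling truncates upward errors for utilities near 1.
This is the iteration-anchoring phenomenon the lead-time TTO literature
itself discusses, and it is well inside the ±0.03 recovery band the test
suite enforces.

## Cleaning rules

Two published rules, applied in order: respondents whose recorded values
are all identical are removed whole (equality is exact — values originate
on the offer grid), then tasks completed within 1 s are dropped
record-by-record. "Completed in just 1 s" is implemented as `≤ 1.0` s, the
inclusive reading of the companion phrase "completed within 1 s". The
all-same rule tests values rather than indifference times because values
are the analysis unit and the arms differ in their T scales. The exclusion
report's identity `records = (participants − all-same) × 5 − fast` assumes
the fast tasks belonged to retained participants; that assumption
reproduces both published record totals (1,834 and 1,891) exactly.

## Analysis choices

* **Grand mean**: the unweighted mean of the ten per-state means — the only
  definition consistent with the published 0.35/0.43 pair given that
  per-state denominators were not printed.
* **Aggregate regression**: OLS of one arm's state means on the other's,
  t-based 95% CIs on `n − 2 = 8` degrees of freedom. On the published China
  means this gives slope 0.936 (CI 0.567–1.306) and intercept −0.056 (CI
  −0.221 to 0.108). The source prints the intercept's upper bound as 0.018;
  OLS on the printed means yields 0.108, and no rounding of the inputs
  produces 0.018, so the printed bound appears to be a digit transposition.
  The package reports the computed interval.
* **Clustered arm comparisons**: continuous outcomes use a linear mixed
  model with a respondent random intercept (REML, Satterthwaite p-values);
  binary outcomes a mixed logistic model, with an automatic fallback to an
  ordinary logistic fit with cluster-robust (respondent-level) standard
  errors when the random-intercept fit fails or does not converge — the
  estimator actually used is recorded in the result. The published account
  names the model family but not the estimator; the random intercept is
  the default because it matches "random effects were built into the
  model". Covariates (age group, gender, education, health state) are
  dropped automatically when constant in the data at hand. p-values are
  two-sided and unadjusted for multiplicity, as in the source analyses.
* **Value bins**: the seven-bin partition of `[−2, 1]` with `{0}` its own
  bin; boundaries are multiples of 0.5 and hence exactly representable, so
  bin membership uses exact comparisons.
* **Display**: values round to 2 decimals and percentages to 1 only at
  print time; all computation is unrounded.

## Verification scale and reproducibility

Everything is seeded and deterministic given the seed; `simulate_study()`
produces byte-identical records on repeated calls, and the pipeline writes
a manifest with seed, versions and per-stage row counts. The test suite
verifies: exact grid recovery by exhaustive enumeration over both arm
grids (102 agents); state-mean recovery within ±0.03 at 400 respondents
per arm, averaged over three replicate studies to damp the max-over-cells
statistic; the sign of the lead-time bias at κ = 0.04, ν = 0.02 over three
replicates; type-I error of the clustered arm test within the binomial 95%
band at 500 replicates of 30 respondents per arm; and the localization of
the engagement effect at γ = 0.6 with 400 respondents per arm. These sizes
were chosen to give Monte-Carlo standard errors comfortably below the
asserted margins while keeping a full run of the suite around a minute.

## Limitations

The continuation of the offer sequence beyond the third question is a
reconstruction, as discussed above; absolute question counts are therefore
comparable to published ones only in distribution, not task by task. Bias
magnitudes (κ, ν, γ) cannot be estimated from public data and the defaults
are illustrative contrasts, not calibrated effect sizes. The censored flag
covers both exhaustion and finer-than-grid indifference; analyses that need
pure exhaustion should additionally condition on `T == 0` (as
`summarize_arm()` does). The simulator implements the *stimulating*
reading of the raised-bar effect (more thought near dead), the
interpretation the source study itself favoured; a confusion reading would
predict the same time pattern but noisier values and is not modelled.
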