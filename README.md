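# leadtto — lead-time time trade-off valuation of EQ-5D-5L health states

Health-state utilities anchor QALY calculations, and the time trade-off
(TTO) is the workhorse method for eliciting them. Conventional TTO needs one
procedure for states better than dead and a different one for states worse
than dead, which puts the two halves of the value scale on doubtful footing.
**Lead-time TTO** fixes this by prefixing the ill period with a span of full
health: the respondent compares Life A — `LT` years in full health followed
by `UT` years in the state being valued — against Life B, `x` years of full
health, and an iterative search finds the indifference duration `T`. The
value of the state is then

```
U = (T − LT) / UT,   U ∈ [−LT/UT, 1]
```

so a single uniform procedure covers values from 1 (full health) through 0
(equivalent to dead, all lead time traded away) down to −LT/UT (tradable
time exhausted). The EuroQol valuation technology (EQ-VT) administers this
by computer for EQ-5D-5L states and time-stamps every answer.

`leadtto` is a toolkit for methodological work on this procedure, aimed at
health-economics researchers designing or auditing valuation studies. It
provides:

* **Value algebra** (`task_config()`, `compute_value()`, `invert_value()`,
  `detectable_resolution()`): the deterministic mapping between indifference
  times and values on the 3-month offer grid.
* **Elicitation engine** (`next_offer()`, `run_task()`, `offer_schedule()`):
  the EQ-VT-style iterative search — openers at values 1 and 0, then grid
  bisection of the preference bracket — with censoring when the grid is
  exhausted before indifference.
* **Synthetic respondents** (`respondent_profile()`, `sample_population()`,
  `simulate_study()`): agents with latent per-state utilities, decision
  noise, an indifference band, a response-time model, and three bias
  mechanisms — lead-time framing (trading more because more is available),
  visual-contrast error (longer bars blunt the length contrast), and a
  raised-bar engagement effect (extra deliberation near the point
  equivalent to dead).
* **QC filters** (`qc_records()`): the standard cleaning rules — drop
  respondents who value every state identically, drop tasks completed
  within 1 s — with auditable exclusion accounting.
* **Arm-comparison analyses** (`summarize_arm()`, `compare_arms()`,
  `aggregate_arm_regression()`, `behavior_by_bin()`, `value_histogram()`):
  per-state and grand summaries, covariate-adjusted mixed-effects arm
  contrasts with respondent-level clustering, the aggregate cross-arm OLS
  on state means, and the seven-bin response-behaviour table.
* **Published reference values** (`eqvt_pilot_means()`,
  `check_reference()`): packaged arm-level summaries from the multinational
  EQ-VT pilot valuation study (China: 10- vs 5-year lead time; Singapore:
  aligned vs raised-bar visual aid), recomputed by the package's own
  analysis code.

## Worked example

A deterministic respondent who values state `53555` at exactly 0.5, walked
through the standard 10 + 5 design:

```r
library(leadtto)
cfg   <- task_config(10, 5)          # value range [-2, 1]
agent <- respondent_profile("r1", true_utilities = c("53555" = 0.5),
                            decision_sd = 0, indifference_tol = 0)
run_task(agent, "53555", cfg)$trace
#>   ordinal     x response
#> 1       1  15   prefer_B      # Life B at value 1: too good
#> 2       2  10   prefer_A      # Life B at value 0: too bad
#> 3       3  12.5 indifferent   # midpoint, value (12.5 - 10)/5 = 0.5
```

Three questions: the two fixed openers, then the bracket midpoint 12.5
years, where `U = 0.5` — the agent's true utility, recovered exactly.

Recomputing the published China-site results from the packaged fixtures:

```r
check_reference("china")
#> Recomputed published arm-level results (china site)
#>   grand mean        : standard 0.35, experimental 0.43
#>   % non-negative    : standard 81.2, experimental 86.7
#>   % exhausted       : standard 0.00, experimental 0.46
#>   records retained  : 1834
#> Aggregate regression on 10 state-mean pairs
#>   y = 0.936 x -0.056
#>   95% CI slope    : 0.567 to 1.306
```

The grand means are unweighted means of the ten per-state means; the
regression fits the standard arm's state means on the experimental arm's —
a slope CI covering 1 and an intercept CI covering 0 mean no aggregate-level
arm difference.

A simulated two-arm study with the framing and visual-contrast biases
switched on, cleaned and compared:

```r
recs <- simulate_study(study_design(200),
                       profile_params(framing_coeff = 0.04,
                                      visual_error_coeff = 0.02),
                       seed = 2026)
qc <- qc_records(recs)                      # 2000 records, none excluded
sapply(split(qc$records, qc$records$arm),
       function(a) summarize_arm(a)$grand_mean)
#> experimental     standard
#>        0.272        0.226
compare_arms(qc$records, "U")
#>   model    : linear mixed (random intercept per respondent)
#>   estimate : 0.0473   p = 0.01671
```

The 10-year-lead-time (standard) arm comes out lower than the 5-year arm,
the direction the bias mechanisms imply, and the clustered model puts the
adjusted difference at about 0.05.

An end-to-end run (`run_pipeline(config, out_dir)`) writes records, the
exclusion report, summaries, the regression, the behaviour table and a
manifest; `inst/scripts/tto-cli.R` wraps the same stages for shell use.

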