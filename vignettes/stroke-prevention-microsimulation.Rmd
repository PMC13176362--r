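---
title: "Methods: microsimulation of primary stroke prevention in type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulation of primary stroke prevention in type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeprev)
```

# The model

`strokeprev` compares enhanced implementations of seven
guideline-recommended stroke-prevention strategies against the status quo
in U.S. adults ≥ 45 years with type 2 diabetes (T2D) and no stroke
history, using an individual-level discrete-time microsimulation with a
one-year cycle. Each simulated year proceeds in a fixed order:

1. **Treatment**: the policy module issues recommendations for the
   scenario's strategies and each individual adopts each recommendation
   independently with the strategy's adherence probability.
2. **Natural history**: age advances one year and HbA1c, SBP/DBP, lipid
   ratio and BMI drift by configured annual slopes.
3. **Events**: cause-specific hazards (stroke, myocardial infarction,
   other-cause death) are computed from risk factors and treatments; a
   competing-risk draw produces at most one transition event.
4. **Accrual**: costs and utilities for the year are recorded.

The ordering itself is a modelling choice: treatment decisions open the
year, and events act on the post-treatment risk-factor levels. States are
`stroke_free`, `acute_stroke` (the year of an event), `post_stroke`,
`dead_stroke` and `dead_other`; dead states are absorbing and accrue
nothing beyond a one-time death cost. An acute stroke kills within the
year with the case-fatality probability, otherwise the individual enters
the chronic post-stroke state, where the stroke hazard is multiplied by a
recurrence factor and other-cause mortality by a post-stroke factor.

## Hazards

The annual stroke hazard is a product of a baseline hazard — log-linear
in age, sex-adjusted, and adjusted for atrial fibrillation, MI history
and the post-stroke state — and per-unit hazard-ratio terms:

$$h = h_0 \cdot \mathrm{HR}_{A1c}^{(\mathrm{ref}-A1c)/1}
      \cdot \mathrm{HR}_{SBP}^{(\mathrm{ref}-SBP)/10}
      \cdot \mathrm{HR}_{lipid}^{(\mathrm{ref}-ratio)/1}
      \cdot \mathrm{HR}_{BMI}^{(\mathrm{ref}-BMI)/1}
      \cdot \prod_j (1 - \mathrm{RRR}_j)$$

Each hazard ratio is defined per unit *decrease* (e.g. per 10 mmHg SBP
reduction), so values above reference raise the hazard; the
$\mathrm{RRR}_j$ are relative risk reductions for aspirin, NOAC (in
atrial fibrillation) and statin therapy. The MI hazard has the same
structure with its own coefficients (lipids weigh more heavily);
other-cause death follows a Gompertz curve times a diabetes multiplier.
Competing risks use the exponential formula: with total hazard $H$, any
event occurs with probability $1 - e^{-H}$ and the cause is drawn with
probability $h_i/H$ — the per-cause probabilities plus $e^{-H}$ sum to
one by construction. The yearly interval means risk factors and
treatments update only once a year; rapid multi-step titration within a
year cannot be represented, which makes treatment-escalation benefits
conservative.

Severe hypoglycemia under insulin (basal or intensive) is drawn as a
Poisson count per year and feeds a per-episode utility decrement only —
the mechanism by which aggressive glycemic escalation can *lose* QALYs
despite averting strokes.

# The synthetic cohort

The generator emulates a national examination-survey T2D subsample
(default n = 1,232, total survey weight 3.7 million; every individual
carries weight `total_weight/n`). Continuous risk factors come from a
Gaussian copula over (age, HbA1c, SBP, lipid ratio, BMI) with
configurable marginals (normal or log-normal) and correlation matrix; the
published source reports only marginal summaries, so the copula is the
simplest joint model with controllable margins. Two features deserve
note:

* **Age truncation.** The cohort enters at age ≥ 45, and the reported
  moments (mean 65.1, SD 9.8) describe the *truncated* distribution.
  Sampling N(65.1, 9.8²) truncated at 45 would inflate the mean by
  ≈ 0.5 years, so the generator numerically solves for the untruncated
  (μ, σ) whose truncated moments equal the configured ones.
* **Achievement-consistent assignment.** Baseline achievement indicators
  for the seven strategies are drawn at the configured national
  proportions, and risk factors and treatment states are made consistent
  with them: BP-controlled individuals have SBP/DBP truncated below
  target and an ACEi/ARB-containing regimen, at-goal HbA1c is truncated
  below the age-specific target, aspirin is assigned among the eligible
  at the rate that yields the national proportion, and anticoagulation is
  assigned within the high-risk AFib subgroup. This makes the criterion
  measurable and exactly recoverable at baseline.

What the generator does **not** emulate: survey design effects (strata
and PSU variance — only point weights are modelled), real covariance
between comorbidities and risk factors beyond the copula block,
informative missingness, and secular trends. Passing generator tests
therefore show that the pipeline reproduces its *configured* population,
not that it reproduces any particular real cohort.

Missing data are introduced missing-completely-at-random per field
(the source does not describe its missingness mechanism) and multiply
imputed by drawing the missing copula coordinates from the conditional
multivariate normal given the observed ones. When achievement targets
truncate marginals, the conditional model ignores the truncation — an
approximation documented here; the imputation oracle tests run the
generator with achievement constraints disabled, where the copula is
exact.

# Policy rules and calibration

The treatment ladders are: glycemic rungs 0–4 (lifestyle, one oral
agent, two oral agents, basal insulin, intensive insulin) and BP rungs
0–6 (half-dose steps up to three full-dose drugs), each with a per-rung
registry effect (defaults 0.7% HbA1c and 5/3 mmHg SBP/DBP per rung).
Statin intensity follows the guideline rule (high for ages 50–70 or
multiple risk factors, moderate at ≥ 75); aspirin eligibility is the
criterion-based rule — age 50–70, at least one additional major ASCVD
risk factor, no high bleeding risk. The alternative "10-year ASCVD risk
> 10%" formulation found in some guideline footnotes conflicts with the
criterion rule; the criterion rule is implemented because it is the one
the strategy definitions themselves use, and its thresholds are
configurable in `guideline_spec()`. Smoking cessation and the weight
programme are one-time year-1 interventions (12% quit success; 5% body
weight loss for BMI > 25), with no relapse or regain beyond natural
drift. Anticoagulation starts a NOAC for untreated AFib with
CHA₂DS₂-VASc ≥ 2; baseline warfarin users are left unchanged, since the
enhancement is defined in terms of NOAC initiation. Congestive heart
failure is not simulated; its CHA₂DS₂-VASc point comes from an optional
baseline flag defaulting to false.

Status-quo adherence is calibrated by bisection: `calibrate_adherence`
fixes one uniform draw per individual, making the achieved proportion a
nondecreasing step function of the adherence probability, so the search
is exact and deterministic. The proportion is measured after the policy
phase of one cycle (recommendation + adoption), before drift and events;
drift over a single year changes achievement negligibly and would make
the objective noisy. Because a finite cohort's baseline achievement
fluctuates around the national target, a sampled cohort can sit slightly
above the target, making it strictly infeasible; `calibrate_all(...,
on_infeasible = "clamp")` returns the nearest boundary with a warning
for that case. The default status-quo adherence vector shipped in the
configuration is illustrative; an analysis should calibrate against its
own cohort.

# Economics

Costs (2022 USD) and utilities are accrued per year and discounted at
3%/year with the first simulation year undiscounted ($t = 0$); the
convention is configurable. There is no half-cycle correction (the model
is annual), and the death year contributes zero utility plus a one-time
death cost. Utilities are baseline minus decrements (acute stroke year,
post-stroke, post-MI, insulin injections/monitoring, per-hypoglycemia
episode), floored at zero.

Scenario contrasts report strokes averted, stroke deaths averted,
incremental cost, incremental QALYs, the ICER with dominance
classification (cost-saving when cheaper and more effective; dominated
when costlier and less effective, reported without a ratio), and the net
health benefit $\mathrm{NHB} = \Delta QALY - \Delta Cost/\lambda$ at
$\lambda$ = \$100,000/QALY, with "highly cost-effective" below
\$50,000/QALY. Uncertainty intervals are the 2.5th/97.5th percentiles of
the replicate-level incremental outcomes pooled across imputations; the
source does not describe how imputation- and replicate-level variability
are combined, and pooled percentiles are the simplest defensible choice
(a Rubin's-rules decomposition is a possible refinement).

# Scenarios, pairing and the experimental design

The catalog is the status quo plus ten enhanced scenarios: seven
single-strategy enhancements (adherence 1.0 for the enhanced strategy,
status quo elsewhere), two combinations, and all seven together.
Combination membership is declared in configuration — defaulting to
{BP, aspirin, statin, smoking} for the first combination and adding
weight loss for the second, the sets found individually cost-saving or
(highly) cost-effective — rather than derived at run time, so the
catalog is static and testable. Partial implementation closes a fraction
$f$ of the adherence gap: $a' = a + f(1-a)$.

Every (imputation m, replicate r) pair owns a common-random-number
stream: fixed-shape uniform arrays indexed by (individual, year,
use-slot), derived from the master seed and (m, r) and reused across
scenarios. Scenario contrasts are therefore paired — a scenario identical
to the status quo produces incremental outcomes that are exactly zero,
and paired uncertainty intervals are strictly narrower than independent
ones. The per-use-slot indexing keeps draws aligned even after
trajectories diverge between scenarios.

The desk-scale default design is n = 1,232 individuals × M = 10
imputations × R = 50 replicates × 11 scenarios over a 10-year horizon
(a lifetime analysis uses 50 years); all four are configurable. The test
suite runs this design end to end; the package's own choice of M and R
keeps Monte-Carlo error in incremental outcomes small relative to the
effects of interest at this cohort size.

One-way sensitivity analysis re-runs a contrast with one registry
parameter pinned at its low or high bound (all else at base), plus a
reduced insulin-price variant that swaps the basal/intensive insulin
annual costs.

# Parameter registry and numerical choices

Every numeric input — baseline hazards, hazard ratios, relative risk
reductions, treatment effects, drift slopes, hypoglycemia rates, costs,
utilities — lives in `inst/extdata/parameters.csv` with base/low/high
values, validated on load (bounds ordered, hazards and costs
non-negative, hazard ratios positive, risk reductions in [0, 1)). The
shipped values are plausible literature-order defaults, not estimates
fitted to any dataset; analyses that depend on absolute magnitudes
should replace them with study-specific values. The package's validation
rests on quantities that do not depend on these defaults: arithmetic
identities (NHB, ICER classification), generator recovery of configured
moments and proportions, closed-form oracles (exponential survival,
annuity discounting, exhaustive score enumeration, all-or-nothing
calibration), and sign/monotonicity properties under protective
treatment effects.

Other numerical choices: risk factors are clamped to physiological
ranges (HbA1c 3.5–19%, SBP 85–240 mmHg, BMI 15–75 kg/m²) after drift and
treatment effects; bisection uses 60 iterations with a default
achievement tolerance of 0.005 (necessarily coarser than one
individual's weight share); copula normal scores are clipped to
(1e-12, 1−1e-12) before quantile transforms; the Cholesky factor adds a
1e-10 diagonal jitter; ties in the cause draw are impossible with
continuous uniforms; an empty population is returned as a zero-row table
with total weight zero.

# Known limitations

* Hazard magnitudes and cost/utility levels are configuration, so
  absolute national projections carry the registry's uncertainty; the
  structure (pairing, identities, monotonicity) is what the tests pin
  down.
* Only the stroke/MI/death pathway of diabetes progression is modelled;
  nephropathy, retinopathy and neuropathy are out of scope, as are newer
  antihyperglycemic agents, pharmacological weight loss, and bleeding
  events beyond the aspirin-eligibility flag.
* Survey variance estimation (design effects) is not implemented; the
  weights act as point expansion factors only.
* The one-year cycle understates the benefit of strategies that in
  practice titrate within months (BP, glycemic control).
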