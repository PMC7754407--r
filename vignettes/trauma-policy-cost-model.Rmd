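---
title: "Modelling the health-economic cost of policy-related childhood trauma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health-economic cost of policy-related childhood trauma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumacost)
```

## The model

`traumacost` estimates what border-control policies that add traumatic
exposure cost per affected child, from a health-sector and a societal
perspective, over 5- and 10-year horizons. The chain has five stages, each
an exported surface that can be used and tested on its own.

### Severity states

Severity is the count of endorsed items on a 14-item checklist of
day-to-day functional impairments (IOS items) observed in trauma-exposed
youth. Counts are binned into four ordinal states — Q1: 0 items, Q2: 1–2,
Q3: 3–4, Q4: more than 4 — plus an absorbing Dead state. In the reference
sample of 458 migrant children the states hold 60/175/134/89 children
(13.1%/38.2%/29.3%/19.4%). `assign_state()` implements the binning;
`tabulate_prevalence()` the state-conditional prevalence of PTSD,
depression, anxiety and ADHD.

One cell of the reference prevalence table is internally inconsistent: the
Q3 depression entry prints a count of 32 against a percentage of 25.37 and
a full-sample count of 109, but 32/134 = 23.88 while 34/134 = 25.37 and
7 + 32 + 34 + 36 = 109. The packaged fixture therefore uses 34, which
reproduces every printed percentage and the marginal total; the printed 32
is treated as a typographical error.

### Trauma dose–response

The association between the number of confirmed trauma types and severity
is a proportional-odds (cumulative logit) regression,

$$\mathrm{logit}\, P(\text{state} > k) \;=\;
\beta_T\,\text{trauma} + \beta_A\,\text{age} + \beta_S\,\text{male} - \zeta_k,
\qquad k = 1,2,3,$$

so $e^{\beta_T}$ is the odds ratio, per additional trauma type, of
occupying a more severe state — above 1 means more severe. Internally the
fit stores cumulative probabilities as $P(\text{state} \le k)$ with the
linear predictor entering negatively; this sign flip is the standard
parameterisation and is absorbed before reporting. The reference estimate
is OR 1.232, 95% CI [1.141, 1.330].

`fit_severity_model()` obtains the maximum-likelihood fit via
`MASS::polr` with a tightened convergence tolerance and returns a classed
object with `coef`, `confint`, `predict` and `summary` methods. The
confidence interval is a Wald interval on the log-odds scale,
exponentiated; the interval method is a package choice (none is stated for
the reference estimate) and Wald is the convention for proportional-odds
fits. The adjustment set is age and sex; sex is coded male = 1, and age
enters linearly in years without centering (the trauma coefficient is
unaffected by either convention). Records missing any model variable are
excluded listwise. The test suite cross-checks the fit against an
independent direct maximisation of the proportional-odds log-likelihood
and verifies 93–97% empirical coverage of the Wald interval over 500
simulated cohorts at n = 458.

### Policy scenarios

Three scenarios assign the fraction of children assumed to experience one
additional policy-related trauma: No Detention 0%, Family Detention 50%,
Zero Tolerance 100%. For the exposed fraction the baseline distribution is
shifted by the proportional-odds transform: at every cut $k$, with
$G_k = P(\text{state} > k)$ among the living,

$$G_k' \;=\; \frac{\mathrm{OR}^{m} G_k}{1 - G_k + \mathrm{OR}^{m} G_k},$$

where $m$ is the number of extra traumas (composing multiplicatively on
the odds scale, consistent with a per-trauma regression coefficient); the
shifted distribution is read back off the transformed cumulative
probabilities and Dead mass is untouched. The scenario's initial
distribution is the mixture
$(1-f)\cdot\text{base} + f\cdot\text{shifted}$. The transform itself is
never written out in the reference account of the model; the cumulative-
odds form above is the canonical reading of "higher odds of starting in a
more severe state" under proportional odds and is stated here as this
package's definition. The shift is applied to the aggregate distribution
rather than child-by-child with re-binning; under proportional odds the
two are equivalent, and the aggregate route is exact and deterministic.

Useful structural facts, all enforced by tests: the shift conserves mass
to 1e-12, first-order stochastically dominates toward severity for
OR > 1, and inverts exactly under OR → 1/OR; the mixture is linear in
$f$, so any linear functional of the trajectory — including every cost
total — is linear in the exposed fraction.

### Markov cohort model

Annual cycles over {Q1..Q4, Dead}. Within a cycle, living mass first
transitions among the four states by a row-stochastic matrix restricted to
advancing progression (no below-diagonal mass; the restriction is a
configuration flag, so matrices that skip states are expressible), then an
age-based fraction of all living mass moves to Dead. The
transitions-then-mortality order within a cycle is a stated contract: the
reference description is silent on it, its effect is second order, and the
order is fixed here for reproducibility. No excess mortality is attached
to more severe states, matching the reference model's explicit exclusion.
No half-cycle correction is applied; costs accrue on start-of-cycle
occupancy. The cohort is tracked at a single representative start age of
13 years (the reference sample mean), configurable.

### Costs and budget impact

Q1 carries the annual cost of a child with no behaviour problems. Q2–Q4
carry the behaviour-problem base cost plus, for each condition, the
condition's annual cost weighted by the state-conditional probability of
carrying the diagnosis. Dead costs nothing. The direct perspective uses
health-sector components only; the societal perspective adds indirect
components (time costs, caregiver absenteeism, transportation). All costs
are annual 2018 USD; `convert_costs()` applies and records a currency or
inflation factor for inputs sourced in other currencies or years.

The reference costing rule assigns Q1 the no-behaviour-problem cost only,
even though some Q1 children carry diagnoses; the package follows that
rule by default and offers `include_q1_conditions = TRUE` for the
alternative reading.

Totals are undiscounted by default — the reference totals are consistent
with undiscounted accumulation and no discount rate is mentioned — with a
configurable rate applied as $1/(1+r)^t$ for standard practice.
Incrementals are computed from unrounded totals and rounded to whole
dollars only in reports; cohort budget impact is the exact product of the
per-child incremental and the cohort size (2,342 / 16,790 / 23,725 by
default). The per-child interval re-runs the entire pipeline at the OR
confidence bounds, varying nothing else.

## The synthetic-cohort generator

The source clinical sample is restricted, so `generate_cohort()` emulates
it. Defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n` | 458 | reference sample size |
| `age_mean`, `age_sd` | 13, 4 years | normal, rounded, clamped to 3–20 |
| `prop_male` | 0.430 | sex margin (male coded 1) |
| `trauma_mean`, `trauma_sd` | 3.6, 2.3 | negative binomial matched by moments, truncated to 0–20 |
| `beta_trauma` | log(1.232) | generating per-trauma log odds |
| `beta_age`, `beta_sex` | 0 | adjustment coefficients |
| `cutpoints` | `"auto"` | calibrated to state shares 60/175/134/89 |
| `prevalence_by_state` | reference table | diagnosis flags given state |
| `seed` | 20180401 | fixture seed |

Choices worth stating. The trauma count uses a negative binomial because
only the mean and SD are published and counts of exposure types are
overdispersed; truncation is by renormalising the pmf on 0–20 (the
20-item instrument bound), which changes the moments negligibly. Ages are
drawn from the discretised normal with boundary mass lumped at 3 and 20;
the induced bias on the mean is below 0.06 years. The adjustment
coefficients default to zero because only the adjusted trauma OR is
published, not the age or sex coefficients; zero keeps the marginal state
shares exactly calibratable while the downstream fit still adjusts for
both covariates. With `cutpoints = "auto"` the three intercepts are solved
by `uniroot` so that the state shares, averaged analytically over the
joint covariate distribution, equal the target shares — so the generated
marginals match the reference sample AND the generating OR is recoverable
by the fit, simultaneously. Severity item counts are drawn uniformly
within the state's bin (only the state, never the raw count, is used
downstream), and diagnosis flags are drawn independently given the state:
the reference table publishes only per-state marginals, so no comorbidity
correlation is modelled — a documented simplification.

What passing tests therefore show about real data: the pipeline's
arithmetic, calibration and estimation machinery are correct under the
stated data-generating process. What they do not show: that real cohorts
satisfy proportional odds exactly, that diagnoses are conditionally
independent, or that the placeholder inputs below match the true service
environment.

## Placeholder inputs and provenance

The annual transition probabilities, age-specific mortality rates, annual
cost components and sensitivity ranges shipped in
`inst/extdata/default_config.yaml` are placeholders of realistic magnitude
and correct structure: the original inputs live in supplementary material
that is not publicly printed. The configuration's `provenance` block
separates reference-derived from placeholder blocks, and
`run_full_analysis()` logs the placeholder list into every run's
`metadata.json`. Consequently the package does not attempt to reproduce
the published absolute per-child totals (e.g. $23,652 direct at 5 years)
or the published per-10% sweep steps ($126/$168) — those depend on the
unavailable inputs. What it does reproduce exactly is everything that
follows arithmetically from published numbers (incrementals, cohort budget
products, the prevalence table, the quartile shares) and every structural
property of the model (scenario ordering, conservation, dominance,
ratchet, sweep linearity, DSA base-case identity).

Two published figures are knowingly inconsistent and are preserved as
findings rather than chased: the Q4 state share prints as 19.5% where the
counts give 19.43%, and the societal Cohort-1 Family Detention product
prints $1,831,440 where 782 × 2,342 = $1,831,444 (asserted to within $5).
Likewise the published societal sweep step ($168 per 10%) exceeds one
tenth of the Zero Tolerance societal incremental ($153.6), which is
incompatible with the exact linearity the mixture construction implies;
the package asserts exact linearity and makes no claim about those step
values. One further adjustment-set ambiguity exists in the reference
account (sex and race versus age and sex); this package adjusts for age
and sex, matching the primary results statement.

## Sensitivity analyses

**One-way DSA.** Each configured input (addressed by a dot-path such as
`costs.conditions.depression.direct`) is set to its low and high value in
turn with everything else at base; the spread is the absolute outcome
difference, and rows are sorted in tornado order. With every parameter at
its base value the base case is reproduced exactly. Under the default
placeholder cost mix the depression direct-cost range dominates the
tornado, mirroring the qualitative finding of the reference analysis.

**Exposed-fraction sweep.** `trauma_fraction_sweep()` runs the pipeline at
exposed fractions 0, 0.1, …, 1. Increments per step are exactly constant
(linearity, above); the test suite asserts equality to 1e-9 relative
tolerance, so any future deviation indicates a bug, not a tolerance.

**PSA.** `run_psa()` samples parameters jointly independently from
families chosen by support — lognormal for the odds ratio (fitted so the
2.5/97.5 quantiles equal the CI bounds: meanlog 0.20855, sdlog 0.03910),
gamma for costs (mean and coefficient of variation), beta for fractions —
re-evaluates the full pipeline per draw, and reports means and 2.5/97.5
percentiles with all draws retained. Families, the 10,000-iteration
default and the seeding policy are package conventions; the reference
account names Monte Carlo simulation without specifics. Degenerate
distributions collapse the PSA to the deterministic result exactly.

## Numerical choices and degenerate inputs

Distributions must sum to 1 within 1e-12 and are validated at every
construction; the Markov engine conserves mass to the same tolerance over
both horizons. Cutpoint calibration solves each intercept to 1e-12 with
`uniroot` on [−60, 60]. The proportional-odds fit tightens `polr`'s
optimiser to a 1e-14 relative tolerance so that independent maximisations
agree to 1e-6 on the trauma coefficient. Empty severity strata in a
prevalence table are flagged `NA`, never zero-filled; cohorts with fewer
than two occupied states or constant trauma counts are rejected with a
diagnostic, as are non-increasing cutpoints, non-stochastic transition
rows, ages beyond the mortality table, and horizons below one cycle.
Ties at bin edges cannot arise (bins partition the integers).

## Problem sizes used by the tests

Calibration checks use generated cohorts of 100,000 (marginal shares to
±0.5%, age mean to ±0.1 years, trauma mean to ±0.05); parameter recovery
uses n = 50,000 (OR to ±0.03) and the oracle equality check n = 200 (to
1e-6); interval coverage uses 500 replicates at n = 458. PSA examples use
2,000–4,000 iterations against closed-form quantiles (±0.01). These sizes
are chosen so each statistical assertion sits several Monte Carlo
standard errors inside its tolerance.

## Known limitations

Trauma is a count of exposure types with no severity grading; diagnoses
are conditionally independent given state; the cohort is tracked at a
single representative age; background (non-policy) trauma accrual is
treated as embodied in the common transition matrix rather than re-applied
per cycle, because the dose–response OR is applied to starting states
only; no detention operating costs, mortality-in-custody, suicide,
substance-use or STD cost extensions are modelled; and no
cost-effectiveness ratios are computed (the model has no effectiveness
denominator — it is a cost and budget-impact model).
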