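---
title: "Modelling the short-term economic burden of gestational diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the short-term economic burden of gestational diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdmburden)
```

## The model

`gdmburden` estimates what a pregnancy complicated by gestational diabetes
mellitus (GDM) costs a national health service over the last trimester,
compared with a euglycemic (normal-glucose) pregnancy. The model is a
probability tree with three cost components per group:

* **Antenatal outpatient care** (deterministic): each resource item —
  screening OGTT, glucose self-monitoring consumables, insulin therapy,
  visits and exams — has a unit cost and a consumption frequency; its cost
  is `unit_cost × consumption_count` over the 90-day horizon. GDM splits
  into diet-treated and insulin-treated subgroups, combined by the insulin
  share (default 0.14).
* **Mother's delivery admission** (chance node): six mutually exclusive
  delivery categories, the DRG codes 370–375, each with a per-group
  probability and a per-group admission cost. The expected cost is the
  probability-weighted sum.
* **Infant's birth admission** (two-level chance node): macrosomia
  (birthweight ≥ 4 kg) first, then exactly one neonatal outcome
  (hypoglycemia, hyperbilirubinemia, shoulder dystocia, respiratory
  distress, brachial plexus injury, or normal newborn), each with a single
  group-independent cost.

Key structural assumptions, inherited from the underlying study design:

* Diagnosis occurs at week 28; the earlier (week 16–18) high-risk pathway
  is out of scope.
* Neonatal outcomes are treated as mutually exclusive and exhaustive; the
  normal-newborn probability is always **computed by difference** so each
  conditional branch sums to one. A real infant can of course have several
  complications, but the per-branch probability vectors are specified to
  exclusive categories and the expected-cost arithmetic relies on that.
* No discounting (horizon < 1 year). Births proxy pregnancies; the national
  case count is `round(births × prevalence)` (half-up).
* Mothers and infants cannot be linked in the discharge data, so infant
  outcome probabilities are literature-derived inputs, never extracted.

`enumerate_tree()` materialises every terminal leaf with its joint
probability; the package's property tests check that this brute-force
expectation equals the closed-form sums for randomised valid parameter
sets, that expectations stay within leaf-cost bounds, and that the model is
affine in every cost.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `horizon_days` | days | 90 | last trimester; the universal multiplier for daily consumption |
| `insulin_share` | proportion | 0.14 | weight of insulin-treated GDM in the GDM outpatient average |
| `gdm_prevalence` | proportion | 0.109 | national prevalence under IADPSG criteria |
| `births` | count | 502,596 | 2014 national births |
| delivery mix | probabilities | count ratios | stored as exact admission-count ratios, not rounded percentages |
| delivery costs | EUR/admission | tariff-based | per group × category |
| outcome costs | EUR/admission | tariff means | group-independent; normal newborn 560 |

Two conventions are worth spelling out:

* **Lower-bound consumption.** Where a frequency is a range ("1–2 shots a
  day", "every 3–4 weeks"), the conservative lower bound is used: ranges in
  shots/day take the lower count, and interval frequencies yield
  `floor((horizon_days / 7) / weeks_high)` events — 6, 3 and 2 visits for
  the 1–2, 3–4 and 5–6 week intervals over 90 days. This floor-at-widest-
  interval rule is locked by tests because it reproduces all printed visit
  totals simultaneously.
* **Money precision.** Costs are carried at full floating precision;
  rounding to 0.1 EUR is a reporting concern only. Delivery probabilities
  are stored as count ratios for the same reason: rounded percentages
  accumulate visible error in the expected costs.

Alternative scenarios are YAML files mirroring the parameter layout
(sections `population`, `outpatient`, `delivery`, `infant`); unspecified
keys fall back to the defaults, unknown keys are an error (typo
protection), and every load is validated with all violations reported at
once. `write_parameters()` inverts `load_parameters()` exactly.

## Sensitivity analyses

**One-way (tornado).** `one_way()` multiplies a single named quantity by
`1 + rel_change` and recomputes both groups' inpatient cost per case.
Perturbing a conditional outcome probability adjusts the normal-newborn
complement so the branch still sums to one; perturbations that would push a
probability outside `[0, 1]` or the complement below zero are errors, not
silent clamps. Outpatient costs are excluded from both sensitivity analyses
by design — the analyses address uncertainty in the administrative-data and
literature inputs, while the outpatient side is a deterministic tariff
calculation; the fixed outpatient difference can be added to any inpatient
delta afterwards.

**Probabilistic (Monte Carlo).** Probabilities are sampled from
beta/Dirichlet distributions and costs from gamma distributions. The
parameterisation is a genuinely open design choice, resolved as follows and
exposed in the `run_psa()` arguments:

* Delivery-mix vectors, for which admission counts exist, are drawn jointly
  from `Dirichlet(counts)` — each marginal is then the natural
  `Beta(successes, failures)` — preserving the sum-to-one constraint.
* Neonatal outcome vectors have no counts, only point probabilities. The
  default draws them jointly from a Dirichlet whose concentration is
  moment-matched so that the largest non-normal component has coefficient
  of variation `prob_cv` (default 0.2, i.e. an assumed standard error of
  20% of the mean); smaller components then carry proportionally wider
  relative uncertainty, the conservative direction. Setting
  `probability_source = "moments"` instead draws independent moment-matched
  betas and renormalises.
* All costs are `Gamma(shape = 1/cv², scale = mean·cv²)`, i.e.
  moment-matched at `cost_cv` (default 0.2). The group-independent neonatal
  outcome costs are drawn **once per iteration and shared between groups**,
  so their uncertainty does not artificially inflate the variance of the
  GDM − euglycemia difference.

Draws are vectorised in a fixed documented order under one root seed, so a
run is exactly reproducible. Because every distribution is mean-preserving,
the Monte Carlo mean converges to the deterministic base case; the tests
check this at 10⁴ iterations (1% band) together with percentile ordering
and seeded determinism. The simulation *extremes* depend entirely on the
assumed spread parameters and are not meaningful reproduction targets.

## Discharge-database extraction

The extraction pipeline mirrors how the model's delivery parameters are
obtained from hospital discharge records:

1. `identify_deliveries()`: keep mother admissions with DRG 370–375;
   childbirth admissions under other DRGs are counted and excluded.
2. `flag_gdm()`: an admission is GDM if ICD9 648.8 appears on the birth
   record or on any admission of the same patient in the window
   `[delivery − 90 d, delivery)`. Records without a patient ID can only be
   flagged through the birth record — the real database lacks unique IDs
   for a material share of records, and the generator reproduces that.
3. `estimate_delivery_mix()`: per-group category counts, normalised.
4. `los_adjusted_cost()`: within each category, drop admissions with a
   length of stay strictly above the category's 99th-percentile LOS
   (nearest-rank on the sorted values; ties at the threshold are retained),
   set `daily_cost = tariff / mean LOS of all remaining women`, and cost
   each group as `daily_cost × group mean LOS`. The percentile filter is
   applied per category because the daily cost is computed per category;
   the overall mean in the denominator includes both groups.
5. `infant_event_costs()`: mean tariff over infant admissions carrying each
   complication's ICD9 code(s) in any diagnosis position, pooling codes
   that map to one model outcome; an outcome with no admissions is reported
   missing, never zero.

ICD9 codes are matched as exact strings in any position of the
semicolon-separated diagnosis field.

## The synthetic cohort generator

Real discharge data cannot ship with the package, so `generate_mothers()`
and `generate_infants()` emulate the statistical structure the extraction
relies on: Bernoulli GDM status, per-group multinomial DRG assignment,
integer lengths of stay from a shifted negative binomial
`1 + NB(mu = mean − 1, size)` (mean exact, right tail heavy enough to
exercise the outlier filter), look-back-only GDM coding on separate prior
admissions, a missing-ID fraction (default 0.091), childbirth admissions
under non-delivery DRGs, and mutually exclusive infant complications with
gamma tariff noise.

`calibrated_cohort_spec()` ties the generator to the packaged model:
delivery probabilities are the default count ratios, and for each DRG
category the GDM mean LOS is solved numerically (`uniroot`) so that the
**post-truncation** LOS ratio equals the target cost ratio, with the tariff
set so the LOS-adjusted costing reproduces the per-category delivery costs
in expectation. Truncated means are computed analytically from the negative
binomial pmf at the population nearest-rank threshold; the euglycemic mean
stays (3–7 days depending on category, caesarean longer than vaginal) are
fixed package choices in the range of observed Italian delivery stays, with
dispersion `size = 10` giving a LOS coefficient of variation around 0.5.

What the generator does *not* emulate: regional coding variation and
under-reporting of the GDM code (the real data show implausibly low coding
rates), calendar seasonality, multiple admissions per pregnancy beyond the
single look-back record, and correlation between mother and infant records
(absent by design). Passing recovery tests therefore show that the
*pipeline* is correct under the assumed data-generating process, not that
the administrative data themselves are unbiased.

## Problem sizes and numerical choices

The test suite runs the PSA at 10⁴ iterations and the extraction recovery
on 10⁵-mother cohorts — sizes at which the checks are statistically
meaningful while the whole suite runs in well under a minute. Only ~11% of
a cohort is GDM, so single-cohort GDM quantities carry a Monte Carlo error
of roughly 0.5–0.7% of their value; point-recovery claims at the 1% level
are therefore evaluated on an estimator averaged over three independent
cohorts (Monte Carlo error ≈ 0.3–0.4%), while per-cell checks use
three-standard-error bands. Rare delivery categories (DRG 374/375 in GDM)
have only tens of admissions per cohort and are only ever assessed against
their own sampling error.

Other numerical conventions: probability-vector sums are validated to
1 ± 1e-9; degenerate beta counts (0 or n successes) are sampled as point
masses; a zero Dirichlet concentration yields an exact zero component; the
GDM case count rounds half-up; and category cells with zero estimated
probability keep their base-case cost on extraction (they cannot influence
an expected cost through a zero-probability branch).

## Known limitations

* The model is national: regional tariff variation is out of scope.
* Out-of-pocket spending, antenatal admissions for GDM complications,
  imperfect compliance and the early-diagnosis pathway are not modelled, so
  the per-case difference is best read as a lower bound.
* Long-term sequelae (type 2 diabetes in mother and child) are outside the
  90-day horizon.
* PSA intervals are conditional on the assumed spread parameters
  (`cost_cv`, `prob_cv`); only the central tendency is a robust output.
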