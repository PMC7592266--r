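---
title: "Estimating chemotherapy volume and budget needs for paediatric ALL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chemotherapy volume and budget needs for paediatric ALL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allquant)
```

## The estimation model

`allquant` implements morbidity-based quantification: national medicine need
is the number of children requiring treatment times the standard full-course
requirement per child, not an extrapolation of past consumption. The
pipeline is deterministic; every step is an explicit arithmetic
transformation of declared inputs, which is what makes the result auditable
for procurement and budgeting.

**Cohort model.** The incident population enters as age-banded counts with
95% uncertainty bounds, separately for diagnosed children and children the
health system fails to diagnose. Two scopes are supported — `diagnosed` and
`diagnosed_plus_undiagnosed` — because the policy questions differ: what the
current system needs versus what universal diagnosis would need. Each band
is split into standard- and high-risk arms by a configured fraction
(epidemiologically, all children diagnosed at 10–14 years are treated as
high risk). A relapse fraction of the scoped incident total then receives a
second treatment course; the relapse split into standard- and high-risk
relapse protocols is independent of the initial arm because relapsed disease
is re-staged. We assume every child completes the full course of the arm it
is allocated to — the estimate answers "what would treating everyone fully
require", so mid-course death or abandonment is deliberately not modelled.

Counts stay fractional through all arithmetic; rounding (half away from
zero) happens only in display tables via `report_counts()`. This is why
sub-totals of displayed tables can disagree with displayed cell sums by one
— the internal values, not the displayed ones, are authoritative.
Uncertainty bounds are propagated by proportional scaling: every operation
in the pipeline is linear in the counts, so scaling bounds by the same
fractions as the point estimate is exact, and no resampling is needed.

**Dosing model.** Chemotherapy doses scale with body size. We use one body
surface area per age band, computed by the Mosteller formula
`sqrt(height_cm × weight_kg / 3600)` from the band's mean height and mean
weight — not the mean of individual BSAs. At national aggregation the
band-mean approach is the natural match for banded incidence data; it does
ignore within-band size variation, which is a known limitation (BSA is a
concave function, so the band-mean BSA slightly overstates the mean of
individual BSAs for a heterogeneous band). Dose rules support three bases —
`per_m2`, `per_kg`, `fixed` — because real protocol sets mix them
(intrathecal methotrexate, for instance, is a fixed age-banded dose).
Treatment phases are carried as rule metadata only: a full-course total does
not depend on phase timing.

**Quantification.** Need per formulation (a medicine–route pair) is summed
over cohorts, then converted to smallest dispensing units — the unit with
the least active ingredient, the common denominator that makes need
comparable to sales. Two rounding policies exist:

* `aggregate` (default): ceiling of the national total. Matches
  sum-to-total-mg-then-present-units estimation, and is the fixture's
  policy.
* `per_patient`: each child's course is rounded up before summation, the
  operationally conservative variant (no sharing of a dispensing unit
  across children). It never yields fewer units than `aggregate`.

Vial sharing and wastage are deliberately *not* modelled at conversion time;
the budget module's wastage scenarios are the mechanism for vial loss.
Sales convert with floor rounding instead: sold packs bound usable units
from below. Sufficiency ratios are only computed for formulations flagged
`predominantly_paediatric_all`, since for medicines dominated by adult
indications the national sales volume says nothing about paediatric supply.

**Budget.** Expenditure is smallest units × list price per unit. List
prices overstate transacted prices, so totals are documented as conservative
maxima. Vial wastage is an additive surcharge `f ×` (parenteral
expenditure): wasting fraction `f` of each vial requires `f` more vials'
worth of spend at the aggregate level, and oral solids are excluded.
Price inflation compounds annually. Scenario analysis re-runs the entire
pipeline per named override (scope, incidence bound, relapse fractions,
wastage), so every scenario figure is produced by the same code path as the
base estimate.

## Parameters that matter

| parameter | units | fixture default | why |
|---|---|---|---|
| `standard_fraction` per band | proportion | 0.65 (0–9 y), 0 (10–14 y) | published risk-group distribution |
| `relapse_count` / `relapse_fraction` | children / proportion | 69 (= 69/318 ≈ 0.217) | published relapse burden; a count input avoids double rounding |
| `standard_relapse_fraction` | proportion | 0.28 | published relapse re-staging split |
| `smallest_unit_strength` | mg or active units | per formulation | denominator of all unit conversions |
| `unit_policy` | – | `aggregate` | see above |
| `health_expenditure_usd` | US$ | 1.7055e10 | denominator of the budget share |
| `wastage_fractions` | proportion | 0.2, 0.4 | vial-loss stress levels |

The relapse fraction is configured, never hard-coded: configurations may
give a relapse *count* (divided by the diagnosed-scope total at load time)
when, as in the packaged case study, the published figure is a count whose
underlying fraction is not printed. The same derived fraction is applied to
both scopes, which reproduces the published combined-scope relapse table.

## The packaged case study and its fixture

`inst/extdata/thai_all_2017/` encodes a published Thai 2017 case study. Its
README labels every number as published, derived or representative. Three
derivations deserve explanation:

* **Fractional incidence reconstruction.** The published per-band integer
  counts do not sum to the published totals (rounding artefacts of the
  source's internal fractional values). The fixture stores fractional
  per-band counts reconstructed from the published percentage shares of the
  published totals; these sum exactly to 318 diagnosed / 215 undiagnosed and
  reproduce the published risk-stratified cells under display rounding.
  One combined-scope cell cannot be made consistent (the publication's own
  combined cells sum to 532, not 533); we prioritised the totals.
* **Needs-from-file budget path.** The national dose schedules behind the
  published unit totals are not public, so the case-study totals cannot be
  recomputed from dose rules. The configuration therefore names a `needs`
  file holding the published smallest-unit totals, and unit prices derived
  as published expenditure ÷ published units. The protocol file ships
  representative doses that reproduce the structure of the guideline (14
  medicines, 16 formulations, 4 arms, BSA-based plus fixed age-banded
  intrathecal dosing), and drives the protocol-based code path in tests and
  synthetic runs.
* **Scenario scaling under file-derived needs.** A relapse-fraction
  override cannot be pushed through a needs file (the file is an aggregate
  over arms), so scenarios scale expenditure by the change in
  course-equivalents `(1 + relapse_fraction)` — i.e. a relapse course is
  costed like an initial course. With protocol-derived needs, scenarios are
  exact full recomputes. This approximation is only as good as the
  relapse-to-initial cost ratio is close to one; it is documented, not
  hidden, and does not affect the base estimates.

## The synthetic generator

`generate_synthetic_inputs(seed, ...)` builds a full input bundle —
incidence with valid bounds, anthropometry, a four-arm protocol set, prices,
and sales constructed as a known multiple of the estimated need — entirely
from one seed. It emulates the *structure* of real inputs and the exact
linear relationships the model asserts (same seed, scale `k` ⇒ all totals
scale by `k`; sales at `k ×` need ⇒ sufficiency exactly `k`). It does not
emulate real-world messiness: no missing strata, no inconsistent published
rounding, no mid-year market entry, no donation channels outside sales
audits. Passing tests on synthetic bundles therefore demonstrate arithmetic
correctness and contract compliance, not robustness to dirty data — the
strict readers and the up-front config cross-validation are the defence
there.

Default sizes (6 medicines, 3 bands, band counts of order 50–200 children)
keep the whole suite, including brute-force per-child oracle comparisons on
cohorts of ≤ 100 children, in the order of seconds.

## Numerical choices and degenerate inputs

* Ceiling/floor conversions carry a `1e-9` tolerance so that exact multiples
  of a unit strength do not round an extra unit up (or down).
* `sufficiency_ratio()` refuses a zero denominator rather than returning
  `Inf`; a medicine with zero estimated need has no meaningful ratio.
* Zero relapse fraction yields an empty relapse cohort table (not rows of
  zeros); aggregation treats formulations never dosed as zero need, and
  `expenditure()` drops all-zero rows before pricing so an absent price for
  an unused formulation is not an error.
* Display conventions mirror the published tables: counts to integers (half
  away from zero), currency to whole dollars, expenditure shares to one
  decimal, health-expenditure share to three decimals, sufficiency ratios to
  one decimal. All stored values are unrounded.

## Known limitations

* One BSA per age band; no within-band or longitudinal growth modelling,
  and only the Mosteller formula is offered.
* Full-course completion is assumed; attrition would lower true need.
* Sales audits missing special procurement channels (e.g. donations) can
  understate supply; the sufficiency ratio inherits that bias.
* The needs-from-file scenario scaling described above.
* Uncertainty bounds are propagated, not modelled: the pipeline's linearity
  makes proportional scaling exact, but correlations between bands inside
  the source microsimulation are unknown, so summed bounds are indicative.
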