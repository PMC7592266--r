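# Thai 2017 paediatric ALL case-study fixture

Encodes a published Thai 2017 case study of chemotherapy volume and budget
needs for paediatric acute lymphoblastic leukaemia, at the level the
published tables print. Provenance of each number:

**Published values** (taken directly from the case-study tables):

- Incidence totals: 318 diagnosed / 215 undiagnosed / 533 combined children
  (0–14 years), and every per-band lower/upper uncertainty bound in
  `incidence.csv`.
- Risk rules (65% standard risk for 0–9 year olds; all 10–14 year olds high
  risk), relapse count (69 diagnosed relapses, split 28% standard / 72% high
  at a second risk assessment) in `config.yaml`.
- Smallest-unit strengths, routes, drug classes, and the smallest-unit
  totals needed per formulation and scope (`needs.csv`, columns
  `smallest_units`).
- Sold-unit totals for the two predominantly-paediatric-ALL medicines:
  asparaginase 10 365 and mercaptopurine 340 035 smallest units in 2017.
- National health expenditure: US$ 17 055 million (2017).

**Derived values** (computed from published values, flagged because the
publication does not print them directly):

- Per-band point counts in `incidence.csv` are fractional reconstructions
  from the published percentage-share column (the published rounded integers
  do not sum to the published totals); they reproduce the published
  risk-stratified cells under display rounding and sum exactly to 318 / 215.
- `prices.csv` unit prices = published diagnosed-scope expenditure divided
  by published diagnosed-scope units, per formulation.
- `needs.csv` milligram totals (= units x strength) and unit bounds
  (= units scaled by the scoped total's bound ratio).

**Synthetic / representative values** (structure-preserving stand-ins):

- `sales.csv` decomposes the two published sold-unit totals into quarterly
  pack-level records (pack sizes and quarterly split are synthetic; the 2017
  totals are exact).
- `protocols.yaml` dose rules are representative magnitudes only — the
  national guideline's dose schedules are not public. The formulary
  structure (14 medicines, 16 formulations, 4 arms) is as published.
- `anthropometry.csv` holds plausible fixture values for mean height/weight
  per age band; the reference table the case study used is not public.
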