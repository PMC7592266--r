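# Run configuration for the Thai 2017 paediatric ALL case study.
year: 2017
scope: diagnosed
files:
  incidence: incidence.csv
  anthropometry: anthropometry.csv
  protocols: protocols.yaml
  prices: prices.csv
  sales: sales.csv
  # Published smallest-unit totals; with this key present the budget and
  # sales-comparison paths use these instead of protocol-derived estimates.
  needs: needs.csv
risk_rules:
  - {age_band: 0-4, standard_fraction: 0.65}
  - {age_band: 5-9, standard_fraction: 0.65}
  # children diagnosed at 10-14 years are high risk by definition
  - {age_band: 10-14, standard_fraction: 0.0}
relapse:
  # 69 of the 318 diagnosed children relapse; divided by the diagnosed total
  # at load time (69/318 = 0.21698...), applied to both population scopes
  relapse_count: 69
  standard_relapse_fraction: 0.28
# US$ 17 055 million
health_expenditure_usd: 1.7055e+10
wastage_fractions: [0.2, 0.4]
unit_policy: aggregate
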