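schema_version: 1
name: flood-plain agricultural investment (case-like)
evaluation_period: 5
finance:
  budget:
    family: point
    value: 89000000.0
    units: USD
  yearly_costs:
  - family: point
    value: 38270000.0
    units: USD
  - family: point
    value: 11480000.0
    units: USD
  - family: point
    value: 13000000.0
    units: USD
  - family: point
    value: 9980000.0
    units: USD
  - family: point
    value: 8860000.0
    units: USD
  discount_rate: 0.05
  reduction_rate: 0.5
  roi_denominator: undiscounted
adoption:
  mode: direct
  scope_basis: beneficiaries
  target_pool:
    family: normal
    mean: 224000.0
    sd: 24072.066187903623359
    units: persons
  yearly_rates:
  - family: beta
    alpha: 4.548127955627408
    beta: 210.895446398195276
    units: fraction
  - family: beta
    alpha: 16.858974566636412
    beta: 163.607678346122128
    units: fraction
  - family: beta
    alpha: 32.444724926712489
    beta: 77.708209799257745
    units: fraction
  - family: beta
    alpha: 33.415265723242022
    beta: 21.764230366160447
    units: fraction
  - family: beta
    alpha: 45.523070607501474
    beta: 4.29734788417093
    units: fraction
impact:
  baseline_income:
    family: normal
    mean: 600.0
    sd: 120.0
    units: USD/beneficiary/yr
  relative_impact:
    family: normal
    mean: 1.463
    sd: 0.589
    units: multiplier
  ghg_balance:
    family: normal
    mean: 0.3
    sd: 0.15
    units: t CO2-eq/beneficiary/yr
  ghg_cost:
    family: uniform
    low: 5.0
    high: 30.0
    units: USD per t CO2-eq
natural_risks:
- name: Drought
  annual_probability: 0.1
  beneficiary_income_multiplier:
    family: uniform
    low: 0.1
    high: 1.0
    units: fraction
  baseline_income_multiplier:
    family: uniform
    low: 0.1
    high: 0.7
    units: fraction
- name: Flood
  annual_probability: 0.1
  beneficiary_income_multiplier:
    family: uniform
    low: 0.2
    high: 1.0
    units: fraction
  baseline_income_multiplier:
    family: uniform
    low: 0.1
    high: 0.7
    units: fraction
- name: Pests
  annual_probability: 0.15
  beneficiary_income_multiplier:
    family: uniform
    low: 1.0e-09
    high: 1.0
    units: fraction
  baseline_income_multiplier:
    family: uniform
    low: 1.0e-09
    high: 0.8
    units: fraction
adoption_risks:
- name: Political crisis
  probability: 0.25
  adoption_rate_effect:
    kind: multiplier
    dist:
      family: uniform
      low: 0.75
      high: 0.85
      units: fraction
  beneficiary_pool_effect:
    kind: multiplier
    dist:
      family: uniform
      low: 0.75
      high: 0.85
      units: fraction
- name: Poor governance
  probability: 0.25
  adoption_rate_effect:
    kind: multiplier
    dist:
      family: uniform
      low: 0.75
      high: 0.85
      units: fraction
  beneficiary_pool_effect:
    kind: multiplier
    dist:
      family: uniform
      low: 0.75
      high: 0.85
      units: fraction
- name: Community conflict
  probability: 0.2
  adoption_rate_effect:
    kind: multiplier
    dist:
      family: uniform
      low: 0.75
      high: 0.85
      units: fraction
  beneficiary_pool_effect:
    kind: multiplier
    dist:
      family: uniform
      low: 0.75
      high: 0.85
      units: fraction
financial_risks: []

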