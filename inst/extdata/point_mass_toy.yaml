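schema_version: 1
name: point-mass toy
evaluation_period: 2
finance:
  budget:
    family: point
    value: 50000.0
    units: USD
  yearly_costs:
  - family: point
    value: 20000.0
    units: USD
  - family: point
    value: 10000.0
    units: USD
  discount_rate: 0.0
  reduction_rate: 0.5
  roi_denominator: undiscounted
adoption:
  mode: direct
  scope_basis: beneficiaries
  target_pool:
    family: point
    value: 1000.0
    units: persons
  yearly_rates:
  - family: point
    value: 0.5
    units: fraction
  - family: point
    value: 1.0
    units: fraction
impact:
  baseline_income:
    family: point
    value: 100.0
    units: USD/beneficiary/yr
  adopter_income:
    family: point
    value: 150.0
    units: USD/beneficiary/yr
  ghg_balance:
    family: point
    value: 0.0
    units: t CO2-eq/beneficiary/yr
  ghg_cost:
    family: point
    value: 0.0
    units: USD per t CO2-eq
natural_risks: []
adoption_risks: []
financial_risks: []

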