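# adcea shipped base-case configuration
# ------------------------------------
# Five-state Markov cohort model of early Alzheimer's disease: annual
# reference (standard-of-care) transition probabilities, age-band all-cause
# mortality with stage mortality hazard ratios, state utilities, costs, and
# the three treatment strategies. Parameters carry their one-way
# sensitivity-analysis limits (osa_ranges) and probabilistic
# sensitivity-analysis distribution families (psa_distributions); an absent
# SE resolves to one tenth of the mean, and family "fixed" never varies.
#
# Derived / assumed entries (not separately published):
#  * strategies.aducanumab.aria_annual and .aria_rate: set equal to the
#    lecanemab values; no aducanumab ARIA row is published. ARIA cost is
#    <0.6% of annual drug cost, so this choice is immaterial.
#  * strategies.aducanumab.admin_annual = 1827.085: administration is a
#    per-infusion fee; lecanemab is infused every 2 weeks (26/yr,
#    3654.17/yr) and aducanumab every 4 weeks (13/yr, half the annual fee).
#  * all three strategies share the treated-cohort starting distribution
#    (61.5% MCI / 38.5% mild) so incremental results compare treatments on
#    a common cohort; the trial placebo split was 66.2% MCI and can be
#    restored via set_param(p, "strategy.soc.start_mci", 0.662).
#  * aducanumab price schedule: 20500 in the first year, 28200 thereafter.
#
discount_rate: 0.03
wtp_default: 150000.0
age_cap: 100.0
stop_tol: 1.0e-06
soc_transitions:
  MCI:
    MILD: 0.32
    MODERATE: 0.04
    SEVERE: 0.01
  MILD:
    MCI: 0.03
    MODERATE: 0.36
    SEVERE: 0.05
  MODERATE:
    MILD: 0.04
    SEVERE: 0.4
  SEVERE:
    MODERATE: 0.02
utilities:
  MCI: 0.73
  MILD: 0.69
  MODERATE: 0.53
  SEVERE: 0.38
mortality:
  age_bands:
  - min_age: 65.0
    max_age: 74.0
    rate: 0.02
  - min_age: 75.0
    max_age: 84.0
    rate: 0.05
  - min_age: 85.0
    max_age: open
    rate: 0.16
  stage_hr:
    MCI: 1.82
    MILD: 2.92
    MODERATE: 3.85
    SEVERE: 9.52
costs:
  outpatient: 3237.26
  inpatient: 17935.84
strategies:
  soc:
    name: soc
    treatment_rule: none
    start_age: 71.0
    start_distribution:
      MCI: 0.615
      MILD: 0.385
    hr_progression: []
    drug_price_schedule: []
    admin_annual: 0.0
    aria_rate: 0.06
    aria_annual: 66.73
    discount_rate: ~
  aducanumab:
    name: aducanumab
    treatment_rule: while_early_AD
    start_age: 71.4
    start_distribution:
      MCI: 0.615
      MILD: 0.385
    hr_progression:
      MCI->MILD: 0.83
    drug_price_schedule:
    - from_cycle: 0
      price: 20500.0
    - from_cycle: 1
      price: 28200.0
    admin_annual: 1827.085
    aria_rate: 0.15
    aria_annual: 154.82
    discount_rate: ~
  lecanemab:
    name: lecanemab
    treatment_rule: while_early_AD
    start_age: 71.4
    start_distribution:
      MCI: 0.615
      MILD: 0.385
    hr_progression:
      MCI->MILD: 0.69
      MILD->MODERATE: 0.69
    drug_price_schedule:
    - from_cycle: 0
      price: 26500.0
    admin_annual: 3654.17
    aria_rate: 0.15
    aria_annual: 154.82
    discount_rate: ~
psa_distributions:
  strategy.lecanemab.hr:
    family: lognormal
    se: ~
  strategy.aducanumab.hr:
    family: lognormal
    se: ~
  transition.MCI.MILD:
    family: beta
    se: ~
  transition.MCI.MODERATE:
    family: beta
    se: ~
  transition.MCI.SEVERE:
    family: beta
    se: ~
  transition.MILD.MCI:
    family: beta
    se: ~
  transition.MILD.MODERATE:
    family: beta
    se: ~
  transition.MILD.SEVERE:
    family: beta
    se: ~
  transition.MODERATE.MILD:
    family: beta
    se: ~
  transition.MODERATE.SEVERE:
    family: beta
    se: ~
  transition.SEVERE.MODERATE:
    family: beta
    se: ~
  utility.MCI:
    family: beta
    se: 0.02
  utility.MILD:
    family: beta
    se: 0.01
  utility.MODERATE:
    family: beta
    se: 0.01
  utility.SEVERE:
    family: beta
    se: 0.01
  cost.outpatient:
    family: gamma
    se: 251.3
  cost.inpatient:
    family: gamma
    se: 1145.99
  strategy.lecanemab.admin_annual:
    family: gamma
    se: ~
  strategy.aducanumab.admin_annual:
    family: gamma
    se: ~
  strategy.lecanemab.aria_annual:
    family: gamma
    se: ~
  strategy.aducanumab.aria_annual:
    family: gamma
    se: ~
  strategy.soc.aria_annual:
    family: gamma
    se: ~
  mortality.hr.MCI:
    family: lognormal
    se: 0.16
  mortality.hr.MILD:
    family: lognormal
    se: 0.19
  mortality.hr.MODERATE:
    family: lognormal
    se: 0.27
  mortality.hr.SEVERE:
    family: lognormal
    se: 0.37
  strategy.lecanemab.price:
    family: fixed
    se: ~
  strategy.aducanumab.price:
    family: fixed
    se: ~
  mortality.rate.65_74:
    family: fixed
    se: ~
  mortality.rate.75_84:
    family: fixed
    se: ~
  mortality.rate.85plus:
    family: fixed
    se: ~
osa_ranges:
  start_age.lecanemab_group:
    low: 65.0
    high: 75.0
  start_age.soc_group:
    low: 65.0
    high: 75.0
  strategy.lecanemab.hr.MCI.MILD:
    low: 0.55
    high: 0.83
  strategy.lecanemab.hr.MILD.MODERATE:
    low: 0.55
    high: 0.83
  strategy.aducanumab.hr.MCI.MILD:
    low: 0.664
    high: 0.996
  transition.MCI.MILD:
    low: 0.26
    high: 0.38
  transition.MCI.MODERATE:
    low: 0.03
    high: 0.05
  transition.MCI.SEVERE:
    low: 0.01
    high: 0.01
  transition.MILD.MCI:
    low: 0.02
    high: 0.04
  transition.MILD.MODERATE:
    low: 0.29
    high: 0.43
  transition.MILD.SEVERE:
    low: 0.04
    high: 0.06
  transition.MODERATE.MILD:
    low: 0.03
    high: 0.05
  transition.MODERATE.SEVERE:
    low: 0.32
    high: 0.48
  transition.SEVERE.MODERATE:
    low: 0.02
    high: 0.02
  strategy.lecanemab.aria_rate:
    low: 0.12
    high: 0.18
  strategy.soc.aria_rate:
    low: 0.05
    high: 0.07
  strategy.lecanemab.price:
    low: 21200.0
    high: 31800.0
  strategy.aducanumab.price:
    low: 16400.0
    high: 24600.0
  strategy.lecanemab.admin_annual:
    low: 2923.34
    high: 4385.01
  strategy.aducanumab.admin_annual:
    low: 1461.67
    high: 2192.5
  cost.outpatient:
    low: 2589.81
    high: 3884.72
  cost.inpatient:
    low: 14348.67
    high: 21523.009999999998
  strategy.lecanemab.aria_annual:
    low: 123.86
    high: 185.78
  strategy.aducanumab.aria_annual:
    low: 123.86
    high: 185.78
  strategy.soc.aria_annual:
    low: 53.39
    high: 80.08
  utility.MCI:
    low: 0.58
    high: 0.88
  utility.MILD:
    low: 0.55
    high: 0.83
  utility.MODERATE:
    low: 0.42
    high: 0.64
  utility.SEVERE:
    low: 0.3
    high: 0.46
  mortality.rate.65_74:
    low: 0.02
    high: 0.03
  mortality.rate.75_84:
    low: 0.04
    high: 0.06
  mortality.rate.85plus:
    low: 0.13
    high: 0.19
  mortality.hr.MCI:
    low: 1.46
    high: 2.18
  mortality.hr.MILD:
    low: 2.34
    high: 3.5
  mortality.hr.MODERATE:
    low: 3.08
    high: 4.62
  mortality.hr.SEVERE:
    low: 7.62
    high: 11.42
  discount.lecanemab_group:
    low: 0.0
    high: 0.08
  discount.soc_group:
    low: 0.0
    high: 0.08
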