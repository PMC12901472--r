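# adcea

Lifetime cost-effectiveness of anti-amyloid antibody therapy in early
Alzheimer's disease (AD), as a reusable, tested R package.

Two anti-amyloid-β monoclonal antibodies have been approved for early AD
(mild cognitive impairment or mild dementia due to AD): aducanumab and
lecanemab. Both are expensive infusion therapies whose clinical benefit is a
modest slowing of progression, so the policy question is not only whether
either is worth its price against standard of care (SoC), but how they
compare with each other. `adcea` implements the standard health-economic
machinery for that question from a US healthcare system perspective:

* a **five-state Markov cohort model** — MCI, mild, moderate and severe
  dementia due to AD, and death — with 1-year cycles over a lifetime
  horizon. Treatment slows progression through a hazard ratio (HR) on the
  affected transitions, converted to annual probabilities; death competes
  first, with age-band all-cause mortality scaled by stage-specific
  mortality HRs;
* **discounted accumulation** (3%/yr) of life-years (LYs), quality-adjusted
  life-years (QALYs, state utilities) and costs (drug, administration, ARIA
  monitoring, outpatient, inpatient);
* **incremental analysis**: for strategies A and B, the incremental
  cost-effectiveness ratio is ICER = (C_A − C_B) / (E_A − E_B) per QALY and
  per LY, with dominance classification and a willingness-to-pay (WTP)
  flag at $150,000/QALY;
* **one-way sensitivity analysis** (tornado) over published parameter
  limits, and **probabilistic sensitivity analysis** (PSA; lognormal HRs,
  beta utilities/probabilities, gamma costs, SE = mean/10 when unreported)
  with cost-effectiveness acceptability curves (CEACs) from net monetary
  benefit, NMB(λ) = λ·ΔQALY − ΔC;
* a **value-based price** solver, a **synthetic instance generator** for
  testing, and CSV reporting functions.

## Worked example

```r
library(adcea)

params <- load_parameters(system.file("extdata", "table1_params.yaml",
                                      package = "adcea"))
fit <- cea_model(params)
fit
```

```
Markov cohort cost-effectiveness model
  hr_method=multiplicative  half_cycle=FALSE  age_cap=100  WTP=150,000 US$/QALY

Incremental analysis (discounted):
              comparison delta_cost delta_ly delta_qaly  icer_per_ly
       aducanumab vs soc  100307.71     0.08       0.08 1,183,178.01
        lecanemab vs soc  130632.68     0.33       0.33   396,315.79
 lecanemab vs aducanumab   30324.97     0.24       0.25   123,856.54
 icer_per_qaly cost_effective
  1,252,560.07          FALSE
    398,240.50          FALSE
    122,306.48           TRUE
```

Reading the output: adding aducanumab to SoC buys 0.08 QALYs for an extra
$100,308 (ICER ≈ $1.25M/QALY); lecanemab buys 0.33 QALYs for $130,633
(ICER ≈ $398k/QALY). Neither is cost-effective against SoC at a
$150,000/QALY threshold. Head to head, lecanemab gains 0.25 QALYs over
aducanumab for $30,325 — an ICER of ≈ $122k/QALY, below the threshold, so
the better of the two antibodies is lecanemab. The annual lecanemab price
that would make it cost-effective against SoC at $150,000/QALY:

```r
value_based_price(params, "lecanemab", "soc", wtp = 150000)
#> [1] 6602.567   # versus the $26,500 list price
```

Sensitivity analyses:

```r
tor <- one_way_sensitivity(params, c("lecanemab", "aducanumab"))
head(tor, 3)        # largest-spread parameters; plot(tor) draws the tornado

psa <- run_psa(params, n_draws = 1000, seed = 1)
cc  <- ceac(psa)    # plot(cc) draws the acceptability curves
ceac_crossing(cc, 0.5, intervention = "aducanumab", reference = "soc")
#> [1] 1220000      # WTP where P(cost-effective vs SoC) reaches 50%
```

File-based reports (`base_case.csv`, `tornado.csv`, `psa_samples.csv`,
`ceac.csv`, `params_audit.csv`, plus a run log recording every resolved
modelling choice) are written by `run_base_case()`, `run_osa()` and
`run_psa_report()` from a `make_run_config()` object.

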