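---
title: "A Markov cohort model for the cost-effectiveness of anti-amyloid therapy in early Alzheimer's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-effectiveness of anti-amyloid therapy in early Alzheimer's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcea)
```

## The decision problem

Aducanumab and lecanemab are intravenous anti-amyloid-β antibodies approved
for early Alzheimer's disease — mild cognitive impairment (MCI) due to AD or
mild dementia due to AD. Both slow clinical progression modestly and cost
tens of thousands of dollars per year. `adcea` evaluates, from a US
healthcare system perspective, whether each antibody added to standard of
care (SoC) is worth its price against SoC alone, and how the two compare
with each other, using the standard cohort-model toolkit of health
economics.

## The model

### States and transitions

A cohort is tracked over five states: `MCI`, `MILD`, `MODERATE`, `SEVERE`
(dementia due to AD) and `DEATH`, in 1-year cycles. The SoC arm's annual
transition probabilities among the alive states are model inputs (e.g.
MCI→mild 0.32/yr, mild→moderate 0.36/yr, moderate→severe 0.40/yr, with
small recovery probabilities such as mild→MCI 0.03/yr). Transitions that
are not listed have probability zero, and the self-transition is never an
input: it is the residual mass of the row.

Treatment acts through a hazard ratio (HR) on specific progression
transitions — lecanemab 0.69 on MCI→mild *and* mild→moderate, aducanumab
0.83 on MCI→mild only — leaving all other transitions unchanged (HR 1).

### Mortality and competing risks

All-cause annual mortality is an age-band input (0.02 for ages 65–74, 0.05
for 75–84, 0.16 at 85+), multiplied by a stage-specific mortality HR (MCI
1.82, mild 2.92, moderate 3.85, severe 9.52) and capped at 1. The cap binds:
severe dementia at 85+ gives 0.16 × 9.52 > 1. For this reason the engine
computes death *first* in every row, then scales each alive→alive
probability by the survivor fraction (1 − p_death) and leaves the residual
on the diagonal. This construction guarantees a row-stochastic matrix for
every admissible input; the engine still asserts a non-negative residual
defensively. Cohort age is deterministic — starting age plus the cycle
index, with band lookup on `floor(age)`; fractional starting ages (71.4 for
the antibody arms, 71.0 for SoC) are kept exact on the age track. No age
mixture within the cohort is modelled.

### Hazard-ratio conversion

Two conversions from an annual probability `p` and an HR `h` are
implemented: the actuarial *rate-based* transform `1 − (1 − p)^h`, and the
*multiplicative* transform `min(1, p·h)`. The published base case this
package reproduces does not state its transform (nor its treatment stopping
rule or half-cycle handling), so we treated those three binary choices as a
calibration: we enumerated transform × stopping rule × half-cycle against
the published incremental results and froze the configuration with the
smallest worst-case relative error. That is the **multiplicative**
transform, treatment **while in early AD**, **no half-cycle correction** —
all nine published incremental quantities are then reproduced within 8%,
most within 2–4%. The multiplicative and rate-based transforms differ
materially here (0.32 × 0.69 = 0.221 versus 1 − 0.68^0.69 = 0.234), and the
calibration clearly prefers the multiplicative one. Both remain available
(`hr_method`), and every reporting function logs which was used.

### Cycle conventions and horizon

Occupancy is recorded at the start of each cycle; transitions happen at the
cycle end; rewards (costs and utilities) attach to start-of-cycle occupancy
discounted by `1/(1+r)^t` with cycle 0 undiscounted. This keeps the full
first year of therapy charged, consistent with an induction year. A
half-cycle correction (half weight on first and last cycle) exists as an
option and is off in the base case, per the calibration above. Simulation
runs to age 100 or an alive fraction below 10⁻⁶, whichever is first; with
the 85+ mortality band the tail beyond 100 is negligible (the shipped
configuration records 29 cycles from age 71.4).

### Costs, utilities, discounting

* Drug prices: lecanemab $26,500/yr flat; aducanumab $20,500 in the first
  year and $28,200 thereafter. Prices follow a per-strategy schedule keyed
  by cycle.
* Administration is a per-infusion fee. Lecanemab is infused every 2 weeks
  (26 infusions/yr, $3,654.17/yr); aducanumab every 4 weeks, so its arm
  accrues half that ($1,827.09/yr). This scheduling detail matters: with a
  single shared administration cost the head-to-head incremental cost is
  understated by roughly $6,000 and cannot match the published base case.
* ARIA (amyloid-related imaging abnormalities) enters as a monitoring cost
  only: one event triggers about three extra MRI scans, so the expected
  annual cost is 3 × MRI unit cost × annual ARIA rate
  (`aria_annual_cost()`). The shipped configuration uses the published
  dollar values directly ($154.82/yr lecanemab arm, $66.73/yr SoC) because
  the two printed dollar values imply slightly inconsistent MRI unit prices
  (344.04 vs 370.72), making the dollars the authoritative encoding. No
  aducanumab ARIA cost is published; it is set equal to the lecanemab value
  (ARIA is <0.6% of annual drug cost, so this is immaterial). For the
  antibody arms ARIA cost rides on the treated fraction; for SoC it is an
  always-on cost on the alive fraction.
* Outpatient ($3,237.26/yr) and inpatient ($17,935.84/yr) costs accrue
  uniformly on the alive fraction; death accrues nothing and no one-off
  dying cost is modelled. SoC accrues no drug or administration cost.
* Utilities: MCI 0.73, mild 0.69, moderate 0.53, severe 0.38; death 0.
* Everything is discounted at 3%/yr; LYs, QALYs and costs are also reported
  undiscounted. All arithmetic is full precision; only presentation rounds.

### The common cohort

The lecanemab trial populations started 61.5% (treated) versus 66.2%
(placebo) in MCI. An incremental comparison, however, is only meaningful on
a common baseline cohort, and the published incremental results are exactly
additive across the three comparisons — the signature of a single cohort
run through three strategies. The shipped configuration therefore starts
all three strategies at 61.5% MCI / 38.5% mild (the treated-arm split,
which the aducanumab arm is also assumed to share), with per-arm starting
ages 71.4/71.4/71.0. With per-arm trial distributions instead, no
combination of the calibration choices above comes close to the published
aducanumab row (errors exceed 70%). The placebo split remains available as
a scenario: `set_param(p, "strategy.soc.start_mci", 0.662)`.

## Sensitivity analyses

### One-way (tornado)

Each parameter with published limits (generally ±20% of the base value;
discount rate 0–8%) is set to its lower and upper limit in turn, the full
base case is re-run (no incremental shortcuts), and the ICER per QALY of
the requested comparison is recorded; bars are sorted by spread. Rows
mirror the published input table: the two lecanemab HRs vary separately;
the two initial-age rows and two discount-rate rows vary the treated arms
jointly versus the SoC arm (the aducanumab cohort is assumed identical to
the lecanemab cohort, so they share those inputs). The aducanumab price
(±20%, scaling both schedule years) and HR rows are not in the published
table but must exist for the tornado to be complete; they are encoded from
the same ±20% rule.

One finding deserves honesty: in any configuration that reproduces the
published incremental results, the ±20% drug-price bars necessarily
dominate the head-to-head tornado — a ±20% lecanemab price shift moves the
incremental cost by ±$21,700 against a 0.25-QALY denominator, an ICER swing
of ≈ $175,000 — ahead of the mild-dementia utility bar (≈ $46,000 spread).
The published ranking (mild-dementia utility first) can only arise if
utilities were varied in one arm at a time, which a shared-utility model
cannot and, we argue, should not do. In our tornado the mild-dementia
utility is the top *utility* driver, with the MCI utility close behind,
consistent with the published narrative once prices are set aside.

### Probabilistic (PSA)

Uncertain parameters are drawn independently, moment-matched so the
distribution mean equals the base value and the SD equals the reported
standard error, or mean/10 when no SE is reported:

* HRs (progression and stage mortality): lognormal with
  σ² = ln(1 + s²/m²), μ = ln m − σ²/2 — so the *mean* (not the median)
  equals the base value;
* utilities and transition probabilities: beta with
  α = m(m(1−m)/s² − 1), β = (1−m)(m(1−m)/s² − 1); transition rows are
  re-validated after drawing and redrawn (with counts kept) if a row sum
  exceeds 1 — essentially never at these SEs;
* costs: gamma with shape (m/s)², scale s²/m;
* fixed in every draw: drug prices, age-band mortality rates, starting ages
  and distributions, and the discount rate.

The two lecanemab progression HRs are perfectly correlated (one draw
applied to both) because a single trial effect underlies them; independent
draws are a configuration away. All draws on one iteration evaluate all
three strategies, so per-draw deltas are additive across comparisons.

CEACs report, per willingness-to-pay value λ on a $0–$2M grid ($10k steps),
the fraction of draws with positive net monetary benefit λ·ΔQALY − ΔC;
`ceac_crossing()` interpolates the WTP where the curve reaches a level
(default 50%). A structural note: with mean-centred draws and an
everywhere-positive ΔQALY, the 50% crossing of a *pairwise* CEAC sits at
the median of the ICER distribution, which is close to the base-case ICER.
Our 1,000-draw PSA accordingly puts the aducanumab-vs-SoC crossing near
$1.2M (base ICER ≈ $1.25M) and the lecanemab-vs-SoC crossing near $400k
(base ICER ≈ $398k); a pairwise crossing far above the base-case ICER would
require the central PSA QALY gain to fall well below its deterministic
value, which mean-centred distributions rule out. Head to head, lecanemab
remains the more likely cost-effective antibody at every WTP from
$150,000/QALY upward (probability ≈ 0.85 at $150k in our runs).

## Synthetic instances and what the tests show

`generate_instance()` produces randomized but structurally valid
configurations: random transition rows with off-diagonal sums below 0.9,
strictly decreasing utilities, a three-band mortality schedule with
increasing rates (keeping the age lookup on every test's hot path), random
non-negative costs, and an intervention with a known ground-truth HR.
`analytic_two_state_fixture()` degenerates the model to a single effective
alive state with constant mortality, whose occupancy is the geometric decay
(1−p)^t and whose discounted life-years have a closed form — an oracle the
engine must match to 10⁻⁶ (and does to machine precision). `recover_hr()`
inverts the engine's transform from a noiseless trace, recovering the true
HR to 10⁻⁹ and flagging transform mismatches.

These instances exercise structure (row-stochasticity, mass conservation,
monotone death occupancy, null-intervention zero deltas), not realism: they
do not emulate trial sampling error, correlated parameters, time-varying
effects or treatment discontinuation. Passing tests therefore certify the
machinery, not the clinical inputs.

Problem sizes in the shipped tests are chosen to keep the full suite around
a minute: 250–1,000 synthetic instances for structural properties, 300
draws for moment-matching convergence (≈ 1/√n), a 1,000-draw seeded PSA for
the acceptability-curve checks, 60–200-cycle fixtures for the analytic
oracle.

## Numerical choices

* Row sums are asserted to 10⁻¹²; occupancy conservation to 10⁻¹⁰.
* The diagonal residual is clamped at 0 against −10⁻¹² float dust; a
  genuinely negative residual raises an error.
* `ceac_crossing()` breaks the never-reached case to a labelled `NA`
  carrying the maximum attained probability; a zero-QALY delta with nonzero
  cost delta yields an "undefined" ICER label, never a division error.
* `value_based_price()` exploits the exact linearity of discounted cost in
  the drug price: one trace, closed-form solve; verified by re-running the
  model at the solved price.
* The PSA seed is a single `set.seed()` at entry; identical seeds give
  bit-identical outputs, and report files embed the seed in their headers.

## Known limitations

* Cohort (not individual-level) simulation: no patient heterogeneity, no
  APOE ε4 subgroups, no time-varying (waning) treatment effect, no
  ARIA-related discontinuation.
* Healthcare-system perspective only: caregiver time and productivity
  losses are out of scope, as are adverse events other than ARIA
  monitoring.
* The head-to-head comparison inherits the limits of an indirect
  comparison: the two antibodies' HRs come from different trials with
  different populations.
* The calibration resolves modelling choices the published base case left
  unstated; the frozen configuration reproduces that base case, but other
  defensible conventions (rate-based transform, half-cycle correction)
  produce materially different absolute ICERs, as the one-way analysis over
  the discount rate and HR method options makes visible.
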