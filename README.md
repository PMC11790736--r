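# aldoCEA

Decision-analytic cost-effectiveness modelling of primary aldosteronism
(PA) treatment strategies for hypertensive patients, from the Japanese
healthcare-payer perspective.

PA is the most common surgically curable cause of hypertension: an
aldosterone-producing adenoma (APA) can be localized by adrenal venous
sampling (AVS) and removed by adrenalectomy or destroyed by radiofrequency
ablation (RFA). Segmental AVS (sAVS) samples the tributaries of the adrenal
veins and localizes adenomas more precisely than conventional AVS (cAVS),
which is what makes image-guided ablation feasible. The package asks
whether the full work-up — screening, confirmatory testing, CT, sAVS, and
surgery or RFA — is worth its upfront cost compared with simply treating
everyone with antihypertensive drugs, for 50-year-old men and women with
stage I–III hypertension.

## Model

The model couples a decision tree for the diagnosis-and-treatment phase
with a four-state Markov cohort model for lifetime follow-up.

**Decision tree.** A strategy partitions the cohort into sub-cohorts with
path probability (mass), one-time cost, annual drug cost and a Markov risk
profile. Five strategies are compared: the comprehensive work-up
(sAVS + RFA), sAVS without RFA, cAVS with RFA, cAVS without RFA, and
medication-only management (PA stays undiagnosed and is treated as
essential hypertension, EHT).

**Markov phase.** States are hypertension, heart failure (HF), stroke and
death, with one-year cycles. Three risk profiles parameterize the annual
exit probabilities from the hypertension state: `cured` (post-treatment),
`pa` (persistent aldosterone excess — markedly higher stroke and HF risk)
and `eht`. Costs (JPY) and utilities accrue per cycle with half-cycle
correction and 2% annual discounting over a horizon equal to remaining
life expectancy (32 years for men, 38 for women).

**Cost-effectiveness.** For strategies S versus reference R,

ICER = (C_S − C_R) / (E_S − E_R)  [JPY per QALY],

judged against a societal willingness-to-pay (WTP) threshold of
5,000,000 JPY/QALY, with dominance classification when the signs make the
ratio unnecessary.

Sensitivity layers: a one-way deterministic analysis over every parameter's
published range (±20% costs, ±8% utilities, ±30% probabilities, 0–4%
discount) with tornado ranking; a horizon sweep locating the life
expectancy at which the comprehensive strategy becomes cost-effective; and
a probabilistic sensitivity analysis sampling beta (probabilities,
utilities) and gamma (costs) distributions by method of moments. An
independent individual-level microsimulation validates the cohort engine.

## Worked example

```r
library(aldoCEA)

params <- default_parameters()
compare_strategies(params, sex = "male")[, c("strategy", "cost", "qaly", "icer")]
#>          strategy    cost     qaly     icer
#> 1   comprehensive 2416017 21.19475 210447.7
#> 2     savs_no_rfa 2418666 21.19475 254199.2
#> 3        cavs_rfa 2429794 21.18741 498425.5
#> 4     cavs_no_rfa 2422373 21.19235 328428.3
#> 5 medication_only 2403275 21.13420       NA
```

The comprehensive work-up costs about 12,700 JPY more than medication-only
management over a man's remaining lifetime but yields 0.061 additional
QALYs, an ICER of about 210,000 JPY/QALY — far below the 5M JPY/QALY
willingness-to-pay threshold, so the work-up is preferred. Among the
work-ups, segmental sampling dominates conventional sampling (better
localization, cheaper downstream), and ablation without segmental guidance
only adds cost.

```r
cycle_sweep(params)
#> ICER falls below 5000000 JPY/QALY at a life expectancy of 8.08 years

tornado(params, "male")[1:3, c("param", "spread")]
#>             param    spread
#> 1        discount 1146123.3
#> 2   prev_apa_savs  818915.8
#> 3 stroke_followup  760374.7

psa(params, "male", n_draws = 10000, seed = 1)
#> probabilistic sensitivity analysis: 10000 draws, 99.4% below the
#> 5000000 JPY/QALY line (0 competing-risk redraws)
```

Patients need a life expectancy of only about eight years for the work-up
to pay off; the discount rate is the most influential single parameter; and
the conclusion is robust under joint parameter uncertainty.

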