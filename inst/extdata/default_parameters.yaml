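# Published point estimates for the primary aldosteronism treatment model.
# Costs in Japanese yen (one-time) or yen per year; probabilities are
# annual where they parameterize the Markov phase.
parameters:
  screening_tests: 17920.0
  ct_avs: 570620.0
  hf_initial: 3463446.0
  stroke_initial: 298855.0
  surgery: 996710.0
  rfa: 677030.0
  drug_eht: 60656.0
  drug_success: 23276.0
  drug_pa_unoperated: 61144.0
  drug_partial_success: 61144.0
  hf_followup: 80755.0
  stroke_followup: 191200.0
  u_eht: 1.0
  u_hf: 0.9
  u_stroke: 0.9
  prev_pa: 0.1
  avs_success: 1.0
  prev_apa_savs: 0.48
  prev_apa_cavs: 0.461
  p_rfa_given_apa: 0.085
  surg_success_savs: 0.84
  surg_success_cavs: 0.802
  rfa_success: 1.0
  drugfree_surgery: 0.44
  drugfree_rfa: 1.0
  cured_death: 0.00416
  cured_hf: 0.0266
  cured_stroke: 0.0011
  pa_death: 0.0042
  pa_hf: 0.0563
  pa_stroke: 0.129
  eht_death: 0.0042
  eht_hf: 0.0266
  eht_stroke: 0.034
  hf_death: 0.0154
  stroke_death: 0.00505
  discount: 0.02
  cycles_male: 32
  cycles_female: 38
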