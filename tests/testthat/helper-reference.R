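# Published cost-effectiveness surface used by the calibration checks:
# expected costs (JPY) and QALYs per strategy and sex, and the
# comprehensive-vs-medication ICERs (JPY per QALY).
reference_results <- function() {
  data.frame(
    strategy = rep(c("comprehensive", "medication_only", "savs_no_rfa",
                     "cavs_rfa", "cavs_no_rfa"), 2),
    sex = rep(c("male", "female"), each = 5),
    cost = c(2708321, 2696803, 2710187, 2714046, 2711855,
             3091802, 3091595, 3093772, 3098474, 3095899),
    qaly = c(21.201, 21.144, 21.201, 21.198, 21.199,
             23.309, 23.248, 23.309, 23.306, 23.306)
  )
}

reference_icers <- function() c(male = 201482, female = 3399)

# independent path-enumeration oracle for the decision tree: explicit
# products along each branch of the comprehensive work-up
enumerate_comprehensive_masses <- function(p) {
  apa <- p$prev_pa * p$avs_success * p$prev_apa_savs
  surg <- apa * (1 - p$p_rfa_given_apa)
  list(
    no_pa = 1 - p$prev_pa,
    avs_failure = p$prev_pa * (1 - p$avs_success),
    bha = p$prev_pa * p$avs_success * (1 - p$prev_apa_savs),
    rfa = apa * p$p_rfa_given_apa,
    surgery_success = surg * p$surg_success_savs,
    surgery_failure = surg * (1 - p$surg_success_savs)
  )
}
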