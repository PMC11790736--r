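test_that("masses sum to one for every strategy, default and random inputs", {
  p <- default_parameters()
  for (s in strategies()$id)
    expect_equal(sum(resolve_strategy(s, p)$mass), 1, tolerance = 1e-12)
  for (seed in 1:10) {
    rp <- random_parameter_set(seed)
    for (s in strategies()$id)
      expect_equal(sum(resolve_strategy(s, rp)$mass), 1, tolerance = 1e-12)
  }
})

test_that("branch masses match the independent path-enumeration oracle", {
  p <- default_parameters()
  sub <- resolve_strategy("comprehensive", p)
  oracle <- enumerate_comprehensive_masses(p)
  expect_equal(oracle$rfa, 0.1 * 1.0 * 0.48 * 0.085) # = 0.00408
  mass_of <- function(prefix) sum(sub$mass[startsWith(sub$label, prefix)])
  expect_equal(mass_of("rfa"), oracle$rfa)
  expect_equal(mass_of("no_pa"), oracle$no_pa)
  expect_equal(mass_of("bha"), oracle$bha)
  expect_equal(mass_of("surgery_drugfree") + mass_of("surgery_success"),
               oracle$surgery_success)
  expect_equal(mass_of("surgery_failure"), oracle$surgery_failure)
})

test_that("medication-only strategy is a two-way split with no upfront cost", {
  p <- default_parameters()
  sub <- resolve_strategy("medication_only", p)
  expect_equal(nrow(sub), 2L)
  expect_setequal(sub$mass, c(0.1, 0.9))
  expect_true(all(sub$upfront_cost == 0))
  expect_true(all(sub$annual_drug_cost == p$drug_eht))
  # undiagnosed PA keeps the elevated risk profile
  expect_equal(sub$risk_profile[sub$label == "pa_undiagnosed"], "pa")
})

test_that("zero prevalence puts all mass in the essential-hypertension leaf", {
  p <- default_parameters(list(prev_pa = 0))
  for (s in strategies()$id) {
    sub <- resolve_strategy(s, p)
    expect_equal(sum(sub$mass[sub$risk_profile == "eht"]), 1)
  }
})

test_that("upfront-cost difference between comprehensive and sAVS-only equals the RFA/surgery swap", {
  for (seed in 1:5) {
    p <- random_parameter_set(seed)
    d <- expected_upfront_cost("comprehensive", p) -
      expected_upfront_cost("savs_no_rfa", p)
    expect_equal(d, p$prev_pa * p$avs_success * p$prev_apa_savs *
                   p$p_rfa_given_apa * (p$rfa - p$surgery),
                 tolerance = 1e-9)
  }
})

test_that("zero RFA uptake collapses comprehensive onto sAVS-without-RFA", {
  p <- default_parameters(list(p_rfa_given_apa = 0))
  a <- resolve_strategy("comprehensive", p)
  b <- resolve_strategy("savs_no_rfa", p)
  expect_equal(a, b)
})

test_that("equal sampling performance makes sAVS and cAVS variants identical", {
  p <- default_parameters(list(prev_apa_cavs = 0.48, surg_success_cavs = 0.84))
  cfg <- model_config(rfa_requires_savs = FALSE)
  expect_equal(resolve_strategy("savs_no_rfa", p, cfg),
               resolve_strategy("cavs_no_rfa", p, cfg))
  a <- resolve_strategy("comprehensive", p, cfg)
  b <- resolve_strategy("cavs_rfa", p, cfg)
  expect_equal(a[order(a$label), -1], b[order(b$label), -1])
})

test_that("ablation without segmental localization costs without curing", {
  p <- default_parameters()
  sub <- resolve_strategy("cavs_rfa", p) # default: rfa_requires_savs = TRUE
  row <- sub[sub$label == "rfa_not_curative", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$risk_profile, "pa")
  expect_equal(row$upfront_cost, p$screening_tests + p$ct_avs + p$rfa)
  expect_equal(row$annual_drug_cost, p$drug_partial_success)
})
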