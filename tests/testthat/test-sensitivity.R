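test_that("tornado endpoints equal an independent re-run of the pipeline", {
  p <- default_parameters()
  tor <- tornado(p, "male", parameters = c("prev_pa", "drug_eht", "discount"))
  for (i in seq_len(nrow(tor))) {
    r <- dsa_range(p, tor$param[i])
    for (side in c("low", "high")) {
      p2 <- p
      p2[[tor$param[i]]] <- r[[side]]
      ev_i <- expected_values("comprehensive", p2, sex = "male")
      ev_r <- expected_values("medication_only", p2, sex = "male")
      expect_equal(tor[[paste0("icer_at_", side)]][i],
                   (ev_i[["cost"]] - ev_r[["cost"]]) /
                     (ev_i[["qaly"]] - ev_r[["qaly"]]),
                   tolerance = 1e-10)
    }
  }
})

test_that("tornado records are sorted by decreasing spread", {
  tor <- tornado(default_parameters(), "male")
  expect_true(!is.unsorted(rev(tor$spread)))
  expect_true(all(tor$spread >= 0))
})

test_that("parameters outside the calibrated cost mapping have zero spread", {
  # the acute-event entry charges are switched off in the shipped default
  tor <- tornado(default_parameters(), "male",
                 parameters = c("hf_initial", "stroke_initial"))
  expect_equal(tor$spread, c(0, 0))
  on <- tornado(default_parameters(), "male",
                parameters = c("hf_initial", "stroke_initial"),
                config = model_config(entry_costs = TRUE))
  expect_true(all(on$spread > 0))
})

test_that("horizon sweep finds a threshold and reacts to treatment costs", {
  p <- default_parameters()
  sw <- cycle_sweep(p)
  expect_true(sw$monotone)
  expect_false(is.na(sw$threshold))
  expect_true(all(diff(sw$grid$icer) < 0))
  # doubling the procedure costs delays cost-effectiveness
  p2 <- default_parameters(list(surgery = p$surgery * 2, rfa = p$rfa * 2))
  sw2 <- cycle_sweep(p2)
  expect_gt(sw2$threshold, sw$threshold)
  # an unreachable threshold yields the no-crossing sentinel
  none <- cycle_sweep(p, config = model_config(wtp = 1), horizons = 1:20)
  expect_true(is.na(none$threshold))
})

test_that("PSA is reproducible under a fixed seed", {
  p <- default_parameters()
  a <- psa(p, "male", n_draws = 50, seed = 42)
  b <- psa(p, "male", n_draws = 50, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(a$fraction_below_wtp, b$fraction_below_wtp)
})

test_that("method-of-moments samplers reproduce the stated moments", {
  set.seed(7)
  n <- 10000
  for (m in c(0.1, 0.44, 0.84)) {
    x <- aldoCEA:::.sample_beta(n, m, 0.10)
    expect_equal(mean(x), m, tolerance = 3 * stats::sd(x) / sqrt(n) / m)
    expect_equal(stats::sd(x) / mean(x), 0.10, tolerance = 0.01)
  }
  y <- aldoCEA:::.sample_gamma(n, 996710, 0.10)
  expect_equal(mean(y), 996710, tolerance = 3 * stats::sd(y) / sqrt(n) / 996710)
  expect_equal(stats::sd(y) / mean(y), 0.10, tolerance = 0.01)
  # degenerate means collapse to the point estimate
  expect_equal(aldoCEA:::.sample_beta(5, 1, 0.1), rep(1, 5))
  expect_equal(aldoCEA:::.sample_beta(5, 0, 0.1), rep(0, 5))
})

test_that("the PSA cloud collapses on the deterministic point as variance shrinks", {
  p <- default_parameters()
  det_i <- expected_values("comprehensive", p, sex = "male")
  det_r <- expected_values("medication_only", p, sex = "male")
  out <- psa(p, "male", n_draws = 40, seed = 9,
             cv_prob = 1e-4, cv_util = 1e-4, cv_cost = 1e-4)
  expect_equal(mean(out$draws$incr_cost), det_i[["cost"]] - det_r[["cost"]],
               tolerance = 1e-2)
  expect_equal(mean(out$draws$incr_qaly), det_i[["qaly"]] - det_r[["qaly"]],
               tolerance = 1e-3)
  expect_lt(stats::sd(out$draws$incr_qaly), 1e-4)
})

test_that("below-WTP flag matches the cost-effectiveness plane geometry", {
  p <- default_parameters()
  out <- psa(p, "male", n_draws = 100, seed = 3)
  d <- out$draws
  expect_identical(d$below_wtp, d$incr_cost < 5e6 * d$incr_qaly)
  expect_equal(out$fraction_below_wtp, mean(d$below_wtp))
})
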