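# Diagnosis-and-treatment phase: each strategy partitions the hypertensive
# cohort into sub-cohorts carrying a one-time upfront cost, an annual drug
# cost and a Markov risk profile.

.strategy_ids <- c("comprehensive", "savs_no_rfa", "cavs_rfa", "cavs_no_rfa",
                   "medication_only")

#' Available treatment strategies
#'
#' Five strategies are compared: the comprehensive work-up (segmental
#' adrenal venous sampling with radiofrequency ablation), three suboptimal
#' work-ups (segmental sampling without ablation, conventional sampling with
#' and without ablation) and medication-only management, in which patients
#' with primary aldosteronism are treated as essential hypertensives.
#'
#' @return A data frame with columns `id`, `uses_savs`, `uses_rfa`,
#'   `is_workup`.
#' @export
strategies <- function() {
  data.frame(
    id = .strategy_ids,
    uses_savs = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    uses_rfa = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    is_workup = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

# fast core used by the evaluation pipeline: parallel vectors, no
# data-frame construction, no re-validation
.resolve_core <- function(strategy, p, config) {
  if (strategy == "medication_only") {
    return(list(
      label = c("pa_undiagnosed", "no_pa"),
      mass = c(p$prev_pa, 1 - p$prev_pa),
      upfront = c(0, 0),
      drug = c(p$drug_eht, p$drug_eht),
      risk = c("pa", "eht")
    ))
  }
  uses_savs <- strategy %in% c("comprehensive", "savs_no_rfa")
  uses_rfa <- strategy %in% c("comprehensive", "cavs_rfa")
  prev_apa <- if (uses_savs) p$prev_apa_savs else p$prev_apa_cavs
  surg_success <- if (uses_savs) p$surg_success_savs else p$surg_success_cavs

  label <- character(0); mass <- numeric(0); upfront <- numeric(0)
  drug <- numeric(0); risk <- character(0)
  add <- function(l, m, u, d, r) {
    label <<- c(label, l); mass <<- c(mass, m); upfront <<- c(upfront, u)
    drug <<- c(drug, d); risk <<- c(risk, r)
  }

  add("no_pa", 1 - p$prev_pa, p$screening_tests, p$drug_eht, "eht")

  workup_cost <- p$screening_tests + p$ct_avs
  # AVS failure: medicated PA (zero mass at the default success rate of 1,
  # but participates when avs_success is varied in sensitivity analysis)
  add("avs_failure", p$prev_pa * (1 - p$avs_success), workup_cost,
      p$drug_pa_unoperated, config$risk_unoperated)
  m_ok <- p$prev_pa * p$avs_success
  # bilateral hyperplasia: not surgically treatable, medicated PA
  add("bha_medicated", m_ok * (1 - prev_apa), workup_cost,
      p$drug_pa_unoperated, config$risk_unoperated)

  m_apa <- m_ok * prev_apa
  frac_rfa <- if (uses_rfa) p$p_rfa_given_apa else 0
  if (frac_rfa > 0) {
    m <- m_apa * frac_rfa
    cost <- workup_cost + p$rfa
    if (uses_savs || !config$rfa_requires_savs) {
      m_s <- m * p$rfa_success
      add("rfa_drugfree", m_s * p$drugfree_rfa, cost, 0, "cured")
      add("rfa_success_drug", m_s * (1 - p$drugfree_rfa), cost,
          p$drug_success, "cured")
      add("rfa_failure", m * (1 - p$rfa_success), cost,
          p$drug_partial_success, config$risk_operated_failure)
    } else {
      # ablation without segmental localization: cost without cure
      add("rfa_not_curative", m, cost, p$drug_partial_success,
          config$risk_unoperated)
    }
  }
  m <- m_apa * (1 - frac_rfa)
  cost <- workup_cost + p$surgery
  m_s <- m * surg_success
  add("surgery_drugfree", m_s * p$drugfree_surgery, cost, 0, "cured")
  add("surgery_success_drug", m_s * (1 - p$drugfree_surgery), cost,
      p$drug_success, "cured")
  add("surgery_failure", m * (1 - surg_success), cost,
      p$drug_partial_success, config$risk_operated_failure)

  list(label = label, mass = mass, upfront = upfront, drug = drug, risk = risk)
}

#' Resolve a strategy into weighted sub-cohorts
#'
#' Walks the decision tree of the diagnosis-and-treatment phase: screening
#' of the whole cohort, CT and adrenal venous sampling (AVS) for the
#' fraction with primary aldosteronism, localization of surgically treatable
#' adenomas, and resection or ablation with PASO-graded outcomes. Each leaf
#' becomes a sub-cohort with its path probability as mass, the sum of the
#' one-time costs along its path, an annual drug cost, and the Markov risk
#' profile it enters.
#'
#' With the default configuration, operated or ablated patients enter the
#' `cured` profile (their clinical-outcome tier setting the drug cost:
#' drug-free, post-success, or partial-success), patients managed medically
#' (bilateral hyperplasia, AVS failures) keep the elevated `pa` profile, and
#' the non-PA majority is `eht`. Ablation after conventional sampling incurs
#' its cost without cure (see [model_config()]).
#'
#' @param strategy One of `"comprehensive"`, `"savs_no_rfa"`, `"cavs_rfa"`,
#'   `"cavs_no_rfa"`, `"medication_only"`.
#' @param params A `pa_parameters` object.
#' @param config A `pa_config` object; defaults to [model_config()].
#' @return A data frame with columns `label`, `mass`, `upfront_cost`,
#'   `annual_drug_cost`, `risk_profile`. Masses sum to 1.
#' @examples
#' resolve_strategy("comprehensive", default_parameters())
#' @export
resolve_strategy <- function(strategy, params, config = model_config()) {
  strategy <- match.arg(strategy, .strategy_ids)
  validate_parameters(params)
  config <- .as_config(config)
  core <- .resolve_core(strategy, params, config)
  out <- data.frame(label = core$label, mass = core$mass,
                    upfront_cost = core$upfront,
                    annual_drug_cost = core$drug,
                    risk_profile = core$risk)
  stopifnot(abs(sum(out$mass) - 1) < 1e-12, all(out$mass >= 0),
            all(out$upfront_cost >= 0))
  out
}

#' Expected upfront cost of a strategy
#'
#' Mass-weighted one-time cost of the diagnosis-and-treatment phase,
#' charged undiscounted at model start.
#'
#' @inheritParams resolve_strategy
#' @return A scalar cost in JPY.
#' @export
expected_upfront_cost <- function(strategy, params, config = model_config()) {
  sub <- resolve_strategy(strategy, params, config)
  sum(sub$mass * sub$upfront_cost)
}
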