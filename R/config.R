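# Structural switches of the model. The defaults are the calibrated
# configuration that reproduces the published cost-effectiveness surface;
# every switch can be flipped to explore alternative conventions.

#' Model configuration
#'
#' Bundles the structural conventions of the decision tree and the Markov
#' engine. The defaults are frozen to the calibrated configuration:
#'
#' * `risk_unoperated = "pa"`: medically managed primary aldosteronism
#'   (bilateral hyperplasia, failed adrenal venous sampling, and RFA
#'   performed without segmental localization) keeps the elevated untreated-PA
#'   risk profile, because aldosterone excess persists under standard
#'   antihypertensive therapy.
#' * `risk_operated_failure = "cured"`: patients whose adenoma was resected
#'   or ablated enter the low-risk cured profile even when blood pressure
#'   control is incomplete; the clinical-outcome tier (complete / partial /
#'   absent success) determines only the annual drug cost.
#' * `rfa_requires_savs = TRUE`: radiofrequency ablation is curative only
#'   when the adenoma was localized by segmental sampling; under conventional
#'   sampling the ablation cost is incurred but the patient remains medicated
#'   PA.
#' * `half_cycle = "standard"`: cycle rewards are computed on the mean of the
#'   state occupancy at the beginning and end of the cycle.
#' * `discount_from = 0`: the reward of cycle t carries discount factor
#'   (1+r)^-(t-1), i.e. the first cycle is undiscounted.
#' * `horizon_inclusive = TRUE`: a horizon of N life-years accrues N+1 cycle
#'   rewards (model stages 0..N inclusive).
#' * `entry_costs = FALSE`: the acute-event costs (`hf_initial`,
#'   `stroke_initial`) are not charged as separate transition rewards; the
#'   chronic states carry their annual follow-up costs only.
#' * `drug_in_event_states = FALSE`: antihypertensive drug costs accrue in
#'   the hypertension state only; the heart-failure and stroke follow-up
#'   costs are treated as all-inclusive.
#'
#' @param risk_unoperated Markov risk profile of medically managed PA:
#'   `"pa"` or `"eht"`.
#' @param risk_operated_failure Profile of operated/ablated patients without
#'   clinical success: `"cured"`, `"eht"` or `"pa"`.
#' @param rfa_requires_savs Logical; if `TRUE`, ablation after conventional
#'   (non-segmental) sampling is non-curative.
#' @param half_cycle `"standard"` (mid-cycle occupancy) or `"none"`
#'   (end-of-cycle occupancy).
#' @param discount_from 0 or 1; exponent offset of the per-cycle discount
#'   factor.
#' @param horizon_inclusive Logical; whether stage 0 and stage N both accrue
#'   rewards (N+1 reward points).
#' @param entry_costs Logical; charge `hf_initial` / `stroke_initial` to the
#'   mass newly entering the heart-failure / stroke state each cycle.
#' @param drug_in_event_states Logical; additionally charge the sub-cohort's
#'   annual drug cost in the heart-failure and stroke states.
#' @param wtp Willingness-to-pay threshold in JPY per QALY.
#' @return A list of class `pa_config`.
#' @export
model_config <- function(risk_unoperated = c("pa", "eht"),
                         risk_operated_failure = c("cured", "eht", "pa"),
                         rfa_requires_savs = TRUE,
                         half_cycle = c("standard", "none"),
                         discount_from = 0,
                         horizon_inclusive = TRUE,
                         entry_costs = FALSE,
                         drug_in_event_states = FALSE,
                         wtp = 5e6) {
  risk_unoperated <- match.arg(risk_unoperated)
  risk_operated_failure <- match.arg(risk_operated_failure)
  half_cycle <- match.arg(half_cycle)
  stopifnot(discount_from %in% c(0, 1), is.logical(rfa_requires_savs),
            is.logical(horizon_inclusive), is.logical(entry_costs),
            is.logical(drug_in_event_states), wtp > 0)
  structure(list(
    risk_unoperated = risk_unoperated,
    risk_operated_failure = risk_operated_failure,
    rfa_requires_savs = rfa_requires_savs,
    half_cycle = half_cycle,
    discount_from = discount_from,
    horizon_inclusive = horizon_inclusive,
    entry_costs = entry_costs,
    drug_in_event_states = drug_in_event_states,
    wtp = wtp
  ), class = "pa_config")
}

.as_config <- function(config) {
  if (is.null(config)) return(model_config())
  if (!inherits(config, "pa_config")) stop("config must come from model_config()")
  config
}

# number of reward points for a stated horizon in life-years
.n_stages <- function(cycles, config) cycles + as.integer(config$horizon_inclusive)

#' Horizon in cycles for a sex
#' @param params A `pa_parameters` object.
#' @param sex `"male"` or `"female"`.
#' @return Integer number of life-years.
#' @export
horizon_for <- function(params, sex = c("male", "female")) {
  sex <- match.arg(sex)
  as.integer(params[[if (sex == "male") "cycles_male" else "cycles_female"]])
}
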