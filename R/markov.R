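# Four-state annual-cycle cohort engine: hypertension, heart failure,
# stroke, death. Heart failure and stroke are chronic absorbing health
# states (their only exit is death); death is absorbing.

.states <- c("htn", "hf", "stroke", "death")

#' Transition matrix for a risk profile
#'
#' Builds the 4x4 row-stochastic annual transition matrix over the states
#' hypertension, heart failure, stroke and death. The hypertension row uses
#' the profile-specific annual risks of heart failure, stroke and death
#' (remainder: stay hypertensive); the heart-failure and stroke rows allow
#' only staying or dying; death is absorbing.
#'
#' @param risk_profile `"cured"`, `"pa"` or `"eht"`.
#' @param params A `pa_parameters` object.
#' @return A 4x4 matrix with dimnames `htn`, `hf`, `stroke`, `death`.
#' @examples
#' transition_matrix("pa", default_parameters())
#' @export
transition_matrix <- function(risk_profile, params) {
  risk_profile <- match.arg(risk_profile, c("cured", "pa", "eht"))
  p_death <- params[[paste0(risk_profile, "_death")]]
  p_hf <- params[[paste0(risk_profile, "_hf")]]
  p_stroke <- params[[paste0(risk_profile, "_stroke")]]
  if (p_death + p_hf + p_stroke > 1)
    stop("competing annual risks for profile '", risk_profile, "' exceed 1")
  P <- rbind(
    c(1 - p_death - p_hf - p_stroke, p_hf, p_stroke, p_death),
    c(0, 1 - params$hf_death, 0, params$hf_death),
    c(0, 0, 1 - params$stroke_death, params$stroke_death),
    c(0, 0, 0, 1)
  )
  dimnames(P) <- list(.states, .states)
  P
}

# state cost / utility vectors for a sub-cohort
.state_costs <- function(drug, params, config) {
  c(drug,
    params$hf_followup + if (config$drug_in_event_states) drug else 0,
    params$stroke_followup + if (config$drug_in_event_states) drug else 0,
    0)
}

.state_utils <- function(params) c(params$u_eht, params$u_hf, params$u_stroke, 0)

#' Run the cohort model for one sub-cohort
#'
#' Propagates a cohort starting fully in the hypertension state through the
#' annual-cycle Markov model and accumulates discounted costs and QALYs.
#' Rewards follow the configured conventions (see [model_config()]): with
#' the default half-cycle correction, the reward of cycle t is computed on
#' the mean of the occupancies at the start and end of the cycle and carries
#' discount factor (1+r)^-(t-1); a horizon of `cycles` life-years accrues
#' `cycles + 1` cycle rewards. The sub-cohort's one-time upfront cost is
#' added undiscounted. All totals are per unit mass.
#'
#' @param risk_profile `"cured"`, `"pa"` or `"eht"`.
#' @param annual_drug_cost Annual drug cost (JPY/year) in the hypertension
#'   state.
#' @param params A `pa_parameters` object.
#' @param cycles Horizon in life-years (positive integer).
#' @param config A `pa_config` object.
#' @param upfront_cost One-time cost added to the cumulative totals.
#' @return A list of class `pa_trace` with the per-cycle trace (`trace`, a
#'   data frame with occupancies, discounted cycle rewards and cumulative
#'   totals) and the totals `cost` and `qaly`.
#' @export
run_cohort <- function(risk_profile, annual_drug_cost, params, cycles,
                       config = model_config(), upfront_cost = 0) {
  stopifnot(cycles >= 1, annual_drug_cost >= 0, upfront_cost >= 0)
  config <- .as_config(config)
  P <- transition_matrix(risk_profile, params)
  sc <- .state_costs(annual_drug_cost, params, config)
  su <- .state_utils(params)
  r <- params$discount
  n <- .n_stages(cycles, config)

  occ <- matrix(NA_real_, n + 1L, 4L, dimnames = list(NULL, .states))
  s <- c(1, 0, 0, 0)
  occ[1L, ] <- s
  cost_d <- qaly_d <- numeric(n)
  for (t in seq_len(n)) {
    new_hf <- s[1L] * P[1L, 2L]
    new_stroke <- s[1L] * P[1L, 3L]
    s2 <- as.vector(s %*% P)
    v <- if (config$half_cycle == "standard") (s + s2) / 2 else s2
    disc <- (1 + r)^-(t - 1L + config$discount_from)
    entry <- if (config$entry_costs)
      new_hf * params$hf_initial + new_stroke * params$stroke_initial else 0
    cost_d[t] <- (sum(v * sc) + entry) * disc
    qaly_d[t] <- sum(v * su) * disc
    s <- s2
    occ[t + 1L, ] <- s
  }
  trace <- data.frame(
    cycle = seq_len(n),
    p_htn = occ[-1L, 1L], p_hf = occ[-1L, 2L],
    p_stroke = occ[-1L, 3L], p_death = occ[-1L, 4L],
    cost_disc = cost_d, qaly_disc = qaly_d,
    cum_cost = upfront_cost + cumsum(cost_d),
    cum_qaly = cumsum(qaly_d)
  )
  structure(list(trace = trace,
                 cost = upfront_cost + sum(cost_d),
                 qaly = sum(qaly_d),
                 risk_profile = risk_profile,
                 cycles = cycles),
            class = "pa_trace")
}

#' @export
print.pa_trace <- function(x, ...) {
  cat(sprintf("Markov cohort trace: profile '%s', %d life-years (%d cycles)\n",
              x$risk_profile, x$cycles, nrow(x$trace)))
  cat(sprintf("  discounted cost %.0f JPY, discounted QALY %.4f\n",
              x$cost, x$qaly))
  invisible(x)
}

# per-profile discounted accumulators reused across sub-cohorts sharing a
# risk profile: intercept terms plus the coefficient of the drug cost, so
# expected values stay linear in each sub-cohort's annual drug cost
.profile_coefs <- function(risk_profile, params, cycles, config) {
  P <- transition_matrix(risk_profile, params)
  su <- .state_utils(params)
  fixed_cost <- .state_costs(0, params, config) # follow-up costs only
  drug_states <- if (config$drug_in_event_states) c(1, 1, 1, 0) else c(1, 0, 0, 0)
  r <- params$discount
  n <- .n_stages(cycles, config)
  s <- c(1, 0, 0, 0)
  cost0 <- drug_coef <- qaly <- 0
  for (t in seq_len(n)) {
    new_hf <- s[1L] * P[1L, 2L]
    new_stroke <- s[1L] * P[1L, 3L]
    s2 <- as.vector(s %*% P)
    v <- if (config$half_cycle == "standard") (s + s2) / 2 else s2
    disc <- (1 + r)^-(t - 1L + config$discount_from)
    entry <- if (config$entry_costs)
      new_hf * params$hf_initial + new_stroke * params$stroke_initial else 0
    cost0 <- cost0 + (sum(v * fixed_cost) + entry) * disc
    drug_coef <- drug_coef + sum(v * drug_states) * disc
    qaly <- qaly + sum(v * su) * disc
    s <- s2
  }
  c(cost0 = cost0, drug_coef = drug_coef, qaly = qaly)
}

#' Expected cost and effectiveness of a strategy
#'
#' Mass-weighted discounted cost and QALY totals over the strategy's
#' sub-cohorts, including upfront costs.
#'
#' @inheritParams resolve_strategy
#' @param cycles Horizon in life-years; if `NULL`, taken from `params` via
#'   `sex`.
#' @param sex `"male"` or `"female"`; used only when `cycles` is `NULL`.
#' @return Named numeric vector `c(cost = ..., qaly = ...)`.
#' @examples
#' expected_values("comprehensive", default_parameters(), sex = "male")
#' @export
expected_values <- function(strategy, params, cycles = NULL,
                            sex = c("male", "female"),
                            config = model_config()) {
  config <- .as_config(config)
  validate_parameters(params)
  strategy <- match.arg(strategy, .strategy_ids)
  if (is.null(cycles)) cycles <- horizon_for(params, match.arg(sex))
  .ev_core(strategy, params, cycles, config)
}

# evaluation core shared by the CEA, DSA and PSA layers; assumes valid inputs
.ev_core <- function(strategy, params, cycles, config) {
  sub <- .resolve_core(strategy, params, config)
  profiles <- unique(sub$risk)
  coefs <- lapply(profiles, .profile_coefs, params = params, cycles = cycles,
                  config = config)
  names(coefs) <- profiles
  cost <- qaly <- 0
  for (i in seq_along(sub$mass)) {
    cf <- coefs[[sub$risk[i]]]
    cost <- cost + sub$mass[i] *
      (sub$upfront[i] + cf[["cost0"]] + sub$drug[i] * cf[["drug_coef"]])
    qaly <- qaly + sub$mass[i] * cf[["qaly"]]
  }
  c(cost = cost, qaly = qaly)
}
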