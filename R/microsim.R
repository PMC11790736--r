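# Individual-level microsimulation oracle. Shares only the parameter set
# and the strategy resolution with the cohort engine; state stepping and
# reward accounting are implemented independently so that the two routes
# can validate each other.

#' Individual-level microsimulation of a strategy
#'
#' Routes each simulated individual through the decision tree by categorical
#' sampling of the branch probabilities (via the resolved sub-cohort
#' masses), then steps it through the Markov phase by per-cycle categorical
#' transitions, applying the same cost, utility and discounting conventions
#' as the cohort engine. Sample means are unbiased estimators of the cohort
#' engine's expected cost and QALYs, which makes this a validation oracle
#' for the deterministic pipeline.
#'
#' @param strategy Strategy id (see [strategies()]).
#' @param params A `pa_parameters` object.
#' @param n_individuals Number of simulated individuals.
#' @param cycles Horizon in life-years; if `NULL`, taken from `sex`.
#' @param sex `"male"` or `"female"`; used only when `cycles` is `NULL`.
#' @param seed Integer seed for reproducibility.
#' @param config A `pa_config` object.
#' @param keep_paths Logical; if `TRUE`, the per-individual state sequences
#'   are returned (an `n_individuals` x (stages+1) integer matrix with
#'   states 1=htn, 2=hf, 3=stroke, 4=death).
#' @return A list of class `pa_microsim`: `mean_cost`, `mean_qaly`,
#'   `se_cost`, `se_qaly`, `n`, sub-cohort assignment counts, and
#'   optionally `paths`.
#' @export
microsimulate <- function(strategy, params, n_individuals = 100000,
                          cycles = NULL, sex = c("male", "female"),
                          seed = NULL, config = model_config(),
                          keep_paths = FALSE) {
  stopifnot(n_individuals >= 1)
  config <- .as_config(config)
  if (is.null(cycles)) cycles <- horizon_for(params, match.arg(sex))
  if (!is.null(seed)) set.seed(seed)

  sub <- resolve_strategy(strategy, params, config)
  n <- as.integer(n_individuals)
  assign_ <- sample.int(nrow(sub), n, replace = TRUE, prob = sub$mass)
  drug <- sub$annual_drug_cost[assign_]
  risk <- sub$risk_profile[assign_]

  # per-individual annual exit probabilities from the hypertension state
  lookup <- function(suffix) {
    v <- c(cured = params[[paste0("cured_", suffix)]],
           pa = params[[paste0("pa_", suffix)]],
           eht = params[[paste0("eht_", suffix)]])
    unname(v[risk])
  }
  p_d <- lookup("death"); p_h <- lookup("hf"); p_s <- lookup("stroke")

  su <- c(params$u_eht, params$u_hf, params$u_stroke, 0)
  half <- config$half_cycle == "standard"
  r <- params$discount
  n_stages <- .n_stages(cycles, config)

  state_cost <- function(st) {
    base <- ifelse(st == 1L, drug,
            ifelse(st == 2L, params$hf_followup,
            ifelse(st == 3L, params$stroke_followup, 0)))
    if (config$drug_in_event_states)
      base <- base + ifelse(st == 2L | st == 3L, drug, 0)
    base
  }

  state <- rep(1L, n)
  cost <- sub$upfront_cost[assign_]
  qaly <- numeric(n)
  paths <- if (keep_paths)
    matrix(NA_integer_, n, n_stages + 1L) else NULL
  if (keep_paths) paths[, 1L] <- state

  for (t in seq_len(n_stages)) {
    u <- stats::runif(n)
    ns <- state
    i1 <- state == 1L
    if (any(i1)) {
      ui <- u[i1]
      ns[i1] <- ifelse(ui < p_d[i1], 4L,
                ifelse(ui < p_d[i1] + p_h[i1], 2L,
                ifelse(ui < p_d[i1] + p_h[i1] + p_s[i1], 3L, 1L)))
    }
    i2 <- state == 2L
    if (any(i2)) ns[i2] <- ifelse(u[i2] < params$hf_death, 4L, 2L)
    i3 <- state == 3L
    if (any(i3)) ns[i3] <- ifelse(u[i3] < params$stroke_death, 4L, 3L)

    disc <- (1 + r)^-(t - 1L + config$discount_from)
    uw <- if (half) (su[state] + su[ns]) / 2 else su[ns]
    cw <- if (half) (state_cost(state) + state_cost(ns)) / 2 else state_cost(ns)
    if (config$entry_costs) {
      cw <- cw + (state == 1L & ns == 2L) * params$hf_initial +
                 (state == 1L & ns == 3L) * params$stroke_initial
    }
    qaly <- qaly + uw * disc
    cost <- cost + cw * disc
    state <- ns
    if (keep_paths) paths[, t + 1L] <- state
  }

  out <- list(
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n), se_qaly = stats::sd(qaly) / sqrt(n),
    n = n, cycles = cycles,
    subcohort_counts = stats::setNames(tabulate(assign_, nrow(sub)), sub$label)
  )
  if (keep_paths) out$paths <- paths
  structure(out, class = "pa_microsim")
}

#' @export
print.pa_microsim <- function(x, ...) {
  cat(sprintf("microsimulation (n = %d, %d life-years):\n", x$n, x$cycles))
  cat(sprintf("  mean cost %.0f JPY (SE %.0f), mean QALY %.4f (SE %.4f)\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Random valid parameter set
#'
#' Draws a structurally valid parameter set for property-based testing:
#' probabilities in \[0, 1\] with feasible competing-risk rows, non-negative
#' costs, utilities in \[0.5, 1\], discount in \[0, 8%\] and horizons of
#' 1-60 years. Values are centred loosely on the defaults but are not meant
#' to be clinically realistic.
#'
#' @param seed Integer seed.
#' @return A validated `pa_parameters` object.
#' @export
random_parameter_set <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- .default_values()
  meta <- .param_meta()
  ov <- list()
  for (id in meta$id) {
    cat_ <- meta$category[meta$id == id]
    ov[[id]] <- switch(cat_,
      cost_initial = ,
      cost_annual = base[[id]] * stats::runif(1, 0.25, 2),
      utility = stats::runif(1, 0.5, 1),
      tree_probability = stats::runif(1, 0, 1),
      transition_probability = stats::runif(1, 0, 0.3),
      discount = stats::runif(1, 0, 0.08),
      cycles = sample(1:60, 1)
    )
  }
  # keep the competing risks leaving hypertension feasible
  for (profile in c("cured", "pa", "eht")) {
    trio <- paste0(profile, c("_death", "_hf", "_stroke"))
    s <- ov[[trio[1]]] + ov[[trio[2]]] + ov[[trio[3]]]
    if (s > 1) for (id in trio) ov[[id]] <- ov[[id]] / (s * 1.01)
  }
  default_parameters(overrides = ov)
}
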