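# Sensitivity layers: one-way deterministic analysis with tornado ranking,
# horizon sweep against the willingness-to-pay threshold, and Monte-Carlo
# probabilistic sensitivity analysis.

.comparison_icer <- function(params, cycles, config,
                             intervention = "comprehensive",
                             reference = "medication_only") {
  ei <- .ev_core(intervention, params, cycles, config)
  er <- .ev_core(reference, params, cycles, config)
  list(icer = (ei[["cost"]] - er[["cost"]]) / (ei[["qaly"]] - er[["qaly"]]),
       incr_cost = ei[["cost"]] - er[["cost"]],
       incr_qaly = ei[["qaly"]] - er[["qaly"]])
}

#' Parameters varied in the one-way deterministic sensitivity analysis
#'
#' All cost, utility, tree and transition probability parameters plus the
#' discount rate; cycle counts are excluded (they are swept separately by
#' [cycle_sweep()]).
#'
#' @param params A `pa_parameters` object.
#' @return Character vector of parameter ids.
#' @export
dsa_parameters <- function(params) {
  meta <- attr(params, "meta")
  meta$id[meta$category != "cycles"]
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the full pipeline with each parameter set to the low and
#' high end of its deterministic range ([dsa_range()]) while all others are
#' held at their point estimates, and records the resulting ICER of the
#' intervention versus the reference. Records are sorted by decreasing
#' spread, the tornado-diagram order.
#'
#' @param params A `pa_parameters` object.
#' @param sex `"male"` or `"female"`.
#' @param intervention,reference Strategy ids.
#' @param parameters Ids to vary; defaults to [dsa_parameters()].
#' @param config A `pa_config` object.
#' @return A data frame of class `pa_tornado` with columns `param`,
#'   `low`, `high` (parameter values), `icer_at_low`, `icer_at_high`,
#'   `spread`, sorted by decreasing spread.
#' @export
tornado <- function(params, sex = c("male", "female"),
                    intervention = "comprehensive",
                    reference = "medication_only",
                    parameters = dsa_parameters(params),
                    config = model_config()) {
  sex <- match.arg(sex)
  config <- .as_config(config)
  cycles <- horizon_for(params, sex)
  rows <- lapply(parameters, function(id) {
    r <- dsa_range(params, id)
    at <- vapply(r, function(v) {
      p2 <- params
      p2[[id]] <- v
      validate_parameters(p2)
      .comparison_icer(p2, cycles, config, intervention, reference)$icer
    }, numeric(1))
    data.frame(param = id, low = r[["low"]], high = r[["high"]],
               icer_at_low = at[[1L]], icer_at_high = at[[2L]],
               spread = abs(at[[2L]] - at[[1L]]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pa_tornado", "data.frame")
  out
}

#' Horizon sweep: life expectancy needed for cost-effectiveness
#'
#' Computes the intervention-versus-reference ICER for every integer model
#' horizon on a grid and locates the fractional horizon (linear
#' interpolation between adjacent integers, 0.01-year resolution) at which
#' the ICER first falls to the willingness-to-pay threshold.
#'
#' The ICER is checked for monotone decrease over the searched horizons;
#' if it is not monotone, all crossings are reported and the first is
#' returned as the threshold.
#'
#' @param params A `pa_parameters` object.
#' @param intervention,reference Strategy ids.
#' @param horizons Integer grid of horizons (life-years) to evaluate.
#' @param config A `pa_config` object; its `wtp` element is the threshold.
#' @return A list of class `pa_sweep`: `grid` (data frame `horizon`,
#'   `icer`), `threshold` (fractional years, `NA` when no crossing),
#'   `crossings`, `monotone`, `wtp`.
#' @export
cycle_sweep <- function(params, intervention = "comprehensive",
                        reference = "medication_only",
                        horizons = 1:50, config = model_config()) {
  config <- .as_config(config)
  stopifnot(all(horizons >= 1), all(horizons == round(horizons)))
  horizons <- sort(unique(as.integer(horizons)))
  icers <- vapply(horizons, function(h)
    .comparison_icer(params, h, config, intervention, reference)$icer,
    numeric(1))
  grid <- data.frame(horizon = horizons, icer = icers)
  wtp <- config$wtp
  below <- icers <= wtp
  crossings <- numeric(0)
  for (i in seq_len(length(horizons) - 1L)) {
    if (!below[i] && below[i + 1L]) {
      frac <- (wtp - icers[i]) / (icers[i + 1L] - icers[i])
      crossings <- c(crossings,
                     round(horizons[i] + frac * (horizons[i + 1L] - horizons[i]), 2))
    }
  }
  threshold <- if (all(below)) horizons[1L]
  else if (length(crossings)) crossings[1L]
  else NA_real_
  structure(list(grid = grid, threshold = threshold, crossings = crossings,
                 monotone = !is.unsorted(rev(icers)), wtp = wtp),
            class = "pa_sweep")
}

#' @export
print.pa_sweep <- function(x, ...) {
  if (is.na(x$threshold))
    cat(sprintf("ICER never falls below %.0f JPY/QALY on the searched horizons\n",
                x$wtp))
  else
    cat(sprintf("ICER falls below %.0f JPY/QALY at a life expectancy of %.2f years\n",
                x$wtp, x$threshold))
  if (!x$monotone)
    cat("note: ICER is not monotone over the grid; crossings: ",
        paste(x$crossings, collapse = ", "), "\n")
  invisible(x)
}

# method-of-moments samplers; cv is the coefficient of variation (sd/mean)
.sample_beta <- function(n, mean, cv) {
  v <- (cv * mean)^2
  if (mean <= 0 || mean >= 1 || v >= mean * (1 - mean)) return(rep(mean, n))
  ab <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * ab, (1 - mean) * ab)
}

.sample_gamma <- function(n, mean, cv) {
  if (mean <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo re-evaluation of the intervention-versus-reference comparison
#' under joint parameter uncertainty. Each draw independently samples every
#' non-fixed parameter by method of moments: probabilities from beta
#' distributions with a coefficient of variation of 10%, utilities from beta
#' distributions with 5%, costs from gamma distributions with 10%.
#' Parameters whose point estimate makes the distribution degenerate (0 or
#' 1 for a beta, 0 for a gamma) are held fixed. Draws in which the competing
#' annual risks of a hypertension row exceed 1 have that row redrawn; the
#' number of redraws is reported.
#'
#' @param params A `pa_parameters` object.
#' @param sex `"male"` or `"female"`.
#' @param n_draws Number of Monte-Carlo samples.
#' @param seed Integer seed for reproducibility.
#' @param intervention,reference Strategy ids.
#' @param config A `pa_config` object; its `wtp` element defines the
#'   cost-effectiveness line.
#' @param cv_prob,cv_util,cv_cost Coefficients of variation (sd/mean) of the
#'   sampled probability, utility and cost distributions.
#' @return A list of class `pa_psa`: `draws` (data frame `draw`,
#'   `incr_cost`, `incr_qaly`, `below_wtp`), `fraction_below_wtp`,
#'   `n_redraws`, `wtp`, `seed`.
#' @export
psa <- function(params, sex = c("male", "female"), n_draws = 10000,
                seed = NULL, intervention = "comprehensive",
                reference = "medication_only", config = model_config(),
                cv_prob = 0.10, cv_util = 0.05, cv_cost = 0.10) {
  sex <- match.arg(sex)
  config <- .as_config(config)
  stopifnot(n_draws >= 1)
  cycles <- horizon_for(params, sex)
  if (!is.null(seed)) set.seed(seed)
  meta <- attr(params, "meta")

  sample_one <- function(id) {
    fam <- meta$psa_family[meta$id == id]
    v <- params[[id]]
    cat_ <- meta$category[meta$id == id]
    switch(fam,
      fixed = rep(v, n_draws),
      beta = .sample_beta(n_draws, v,
                          if (cat_ == "utility") cv_util else cv_prob),
      gamma = .sample_gamma(n_draws, v, cv_cost))
  }
  ids <- meta$id
  draws <- lapply(ids, sample_one)
  names(draws) <- ids

  # redraw hypertension rows whose competing risks exceed 1
  n_redraws <- 0L
  for (profile in c("cured", "pa", "eht")) {
    trio <- paste0(profile, c("_death", "_hf", "_stroke"))
    repeat {
      bad <- which(draws[[trio[1]]] + draws[[trio[2]]] + draws[[trio[3]]] > 1)
      if (!length(bad)) break
      n_redraws <- n_redraws + length(bad)
      for (id in trio) {
        fam <- meta$psa_family[meta$id == id]
        if (fam == "beta")
          draws[[id]][bad] <- .sample_beta(length(bad), params[[id]], cv_prob)
      }
    }
  }

  incr_cost <- incr_qaly <- numeric(n_draws)
  p2 <- params
  for (k in seq_len(n_draws)) {
    for (id in ids) p2[[id]] <- draws[[id]][k]
    cmp <- .comparison_icer(p2, cycles, config, intervention, reference)
    incr_cost[k] <- cmp$incr_cost
    incr_qaly[k] <- cmp$incr_qaly
  }
  below <- incr_cost < config$wtp * incr_qaly
  structure(list(
    draws = data.frame(draw = seq_len(n_draws), incr_cost = incr_cost,
                       incr_qaly = incr_qaly, below_wtp = below),
    fraction_below_wtp = mean(below),
    n_redraws = n_redraws,
    wtp = config$wtp,
    seed = seed
  ), class = "pa_psa")
}

#' @export
print.pa_psa <- function(x, ...) {
  cat(sprintf("probabilistic sensitivity analysis: %d draws, %.1f%% below the %.0f JPY/QALY line (%d competing-risk redraws)\n",
              nrow(x$draws), 100 * x$fraction_below_wtp, x$wtp, x$n_redraws))
  invisible(x)
}
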