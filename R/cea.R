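# Incremental cost-effectiveness layer: ICERs, dominance classification and
# willingness-to-pay preference.

#' Incremental cost-effectiveness ratio
#'
#' Compares an intervention with a reference evaluated on the same
#' parameters and horizon. When the intervention is cheaper and more
#' effective it dominates (no ICER); when costlier and less effective it is
#' dominated. Otherwise ICER = incremental cost / incremental QALYs, and the
#' intervention is preferred when it dominates or its ICER is at most the
#' willingness-to-pay threshold (inclusive).
#'
#' @param intervention,reference Named numeric vectors with elements `cost`
#'   and `qaly`, as returned by [expected_values()].
#' @param wtp Willingness-to-pay threshold in JPY per QALY.
#' @return A list of class `pa_icer`: `incr_cost`, `incr_qaly`, `icer`
#'   (`NA` under dominance or when undefined), `classification` (one of
#'   `"dominant"`, `"dominated"`, `"icer"`, `"undefined"`) and `preferred`.
#' @examples
#' icer(c(cost = 110, qaly = 2.1), c(cost = 100, qaly = 2.0), wtp = 500)
#' @export
icer <- function(intervention, reference, wtp = 5e6) {
  dc <- unname(intervention[["cost"]] - reference[["cost"]])
  de <- unname(intervention[["qaly"]] - reference[["qaly"]])
  if (dc < 0 && de > 0) {
    out <- list(icer = NA_real_, classification = "dominant", preferred = TRUE)
  } else if (dc > 0 && de < 0) {
    out <- list(icer = NA_real_, classification = "dominated", preferred = FALSE)
  } else if (de == 0) {
    out <- list(icer = NA_real_, classification = "undefined",
                preferred = dc <= 0)
  } else {
    ratio <- dc / de
    # de < 0 with dc <= 0: ratio measures savings per QALY forgone;
    # preference at the threshold still compares against wtp
    preferred <- if (de > 0) ratio <= wtp else ratio > wtp
    out <- list(icer = ratio, classification = "icer", preferred = preferred)
  }
  structure(c(list(incr_cost = dc, incr_qaly = de), out, list(wtp = wtp)),
            class = "pa_icer")
}

#' @export
print.pa_icer <- function(x, ...) {
  cat(sprintf("incremental cost %.0f JPY, incremental QALY %.5f\n",
              x$incr_cost, x$incr_qaly))
  if (x$classification == "icer")
    cat(sprintf("ICER %.0f JPY/QALY (WTP %.0f): %s\n", x$icer, x$wtp,
                if (x$preferred) "preferred" else "not preferred"))
  else
    cat(sprintf("%s (%s)\n", x$classification,
                if (x$preferred) "preferred" else "not preferred"))
  invisible(x)
}

#' Compare all strategies against medication-only management
#'
#' Evaluates the five strategies and reports expected cost, expected QALYs,
#' and increments, ICER, dominance classification and willingness-to-pay
#' preference versus the medication-only reference.
#'
#' @param params A `pa_parameters` object.
#' @param sex `"male"` or `"female"` (sets the horizon).
#' @param cycles Optional explicit horizon overriding `sex`.
#' @param config A `pa_config` object.
#' @return A data frame with one row per strategy, the reference row first.
#' @examples
#' compare_strategies(default_parameters(), sex = "male")
#' @export
compare_strategies <- function(params, sex = c("male", "female"),
                               cycles = NULL, config = model_config()) {
  sex <- match.arg(sex)
  config <- .as_config(config)
  if (is.null(cycles)) cycles <- horizon_for(params, sex)
  ev <- lapply(.strategy_ids, expected_values, params = params,
               cycles = cycles, config = config)
  names(ev) <- .strategy_ids
  ref <- ev[["medication_only"]]
  rows <- lapply(.strategy_ids, function(id) {
    e <- ev[[id]]
    if (id == "medication_only") {
      data.frame(strategy = id, sex = sex, cost = e[["cost"]],
                 qaly = e[["qaly"]], incr_cost = NA_real_,
                 incr_qaly = NA_real_, icer = NA_real_,
                 classification = "reference", preferred = NA)
    } else {
      ic <- icer(e, ref, wtp = config$wtp)
      data.frame(strategy = id, sex = sex, cost = e[["cost"]],
                 qaly = e[["qaly"]], incr_cost = ic$incr_cost,
                 incr_qaly = ic$incr_qaly, icer = ic$icer,
                 classification = ic$classification, preferred = ic$preferred)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
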