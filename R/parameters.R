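# Parameter set: every model input with units, deterministic sensitivity
# range and probabilistic sensitivity distribution family.

.param_meta <- function() {
  m <- rbind(
    # id,                    units,                  category,                 psa_family
    c("screening_tests",     "JPY",                  "cost_initial",           "gamma"),
    c("ct_avs",              "JPY",                  "cost_initial",           "gamma"),
    c("hf_initial",          "JPY",                  "cost_initial",           "gamma"),
    c("stroke_initial",      "JPY",                  "cost_initial",           "gamma"),
    c("surgery",             "JPY",                  "cost_initial",           "gamma"),
    c("rfa",                 "JPY",                  "cost_initial",           "gamma"),
    c("drug_eht",            "JPY_per_year",         "cost_annual",            "gamma"),
    c("drug_success",        "JPY_per_year",         "cost_annual",            "gamma"),
    c("drug_pa_unoperated",  "JPY_per_year",         "cost_annual",            "gamma"),
    c("drug_partial_success","JPY_per_year",         "cost_annual",            "gamma"),
    c("hf_followup",         "JPY_per_year",         "cost_annual",            "gamma"),
    c("stroke_followup",     "JPY_per_year",         "cost_annual",            "gamma"),
    c("u_eht",               "utility",              "utility",                "fixed"),
    c("u_hf",                "utility",              "utility",                "beta"),
    c("u_stroke",            "utility",              "utility",                "beta"),
    c("prev_pa",             "probability",          "tree_probability",       "beta"),
    c("avs_success",         "probability",          "tree_probability",       "fixed"),
    c("prev_apa_savs",       "probability",          "tree_probability",       "beta"),
    c("prev_apa_cavs",       "probability",          "tree_probability",       "beta"),
    c("p_rfa_given_apa",     "probability",          "tree_probability",       "beta"),
    c("surg_success_savs",   "probability",          "tree_probability",       "beta"),
    c("surg_success_cavs",   "probability",          "tree_probability",       "beta"),
    c("rfa_success",         "probability",          "tree_probability",       "fixed"),
    c("drugfree_surgery",    "probability",          "tree_probability",       "beta"),
    c("drugfree_rfa",        "probability",          "tree_probability",       "fixed"),
    c("cured_death",         "probability_per_year", "transition_probability", "beta"),
    c("cured_hf",            "probability_per_year", "transition_probability", "beta"),
    c("cured_stroke",        "probability_per_year", "transition_probability", "beta"),
    c("pa_death",            "probability_per_year", "transition_probability", "beta"),
    c("pa_hf",               "probability_per_year", "transition_probability", "beta"),
    c("pa_stroke",           "probability_per_year", "transition_probability", "beta"),
    c("eht_death",           "probability_per_year", "transition_probability", "beta"),
    c("eht_hf",              "probability_per_year", "transition_probability", "beta"),
    c("eht_stroke",          "probability_per_year", "transition_probability", "beta"),
    c("hf_death",            "probability_per_year", "transition_probability", "beta"),
    c("stroke_death",        "probability_per_year", "transition_probability", "beta"),
    c("discount",            "per_year",             "discount",               "fixed"),
    c("cycles_male",         "years",                "cycles",                 "fixed"),
    c("cycles_female",       "years",                "cycles",                 "fixed")
  )
  data.frame(id = m[, 1], units = m[, 2], category = m[, 3],
             psa_family = m[, 4], stringsAsFactors = FALSE)
}

.default_values <- function() {
  list(
    screening_tests = 17920, ct_avs = 570620, hf_initial = 3463446,
    stroke_initial = 298855, surgery = 996710, rfa = 677030,
    drug_eht = 60656, drug_success = 23276, drug_pa_unoperated = 61144,
    drug_partial_success = 61144, hf_followup = 80755, stroke_followup = 191200,
    u_eht = 1.0, u_hf = 0.9, u_stroke = 0.9,
    prev_pa = 0.1, avs_success = 1.0, prev_apa_savs = 0.48,
    prev_apa_cavs = 0.461, p_rfa_given_apa = 0.085,
    surg_success_savs = 0.84, surg_success_cavs = 0.802,
    rfa_success = 1.0, drugfree_surgery = 0.44, drugfree_rfa = 1.0,
    cured_death = 0.00416, cured_hf = 0.0266, cured_stroke = 0.0011,
    pa_death = 0.0042, pa_hf = 0.0563, pa_stroke = 0.129,
    eht_death = 0.0042, eht_hf = 0.0266, eht_stroke = 0.034,
    hf_death = 0.0154, stroke_death = 0.00505,
    discount = 0.02, cycles_male = 32, cycles_female = 38
  )
}

#' Default model parameter set
#'
#' Returns the published point estimates used throughout the model: one-time
#' and annual costs in Japanese yen, state utilities, decision-tree branch
#' probabilities, annual Markov transition probabilities, the annual discount
#' rate (2%) and the model horizons (expected remaining life-years of
#' 50-year-old Japanese men and women: 32 and 38 years).
#'
#' Probability parameters cover the diagnostic work-up (prevalence of primary
#' aldosteronism among hypertensives, adrenal venous sampling success,
#' prevalence of surgically treatable aldosterone-producing adenoma under
#' segmental and conventional sampling, the fraction of adenomas ablated
#' rather than resected, treatment success and drug-free rates) and the
#' four-state Markov phase (annual risks of heart failure, stroke and death
#' for cured, untreated-PA and essential-hypertension risk profiles, plus
#' annual case fatality in the heart-failure and stroke states).
#'
#' @param overrides Named list of parameter values replacing the defaults.
#' @return An object of class `pa_parameters`: a named list of scalar values
#'   with a `meta` attribute describing units, category and probabilistic
#'   sensitivity family of each parameter.
#' @examples
#' p <- default_parameters()
#' p$surgery
#' dsa_range(p, "prev_pa")
#' @export
default_parameters <- function(overrides = list()) {
  vals <- .default_values()
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(vals))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    vals[names(overrides)] <- overrides
  }
  params <- structure(vals, class = "pa_parameters", meta = .param_meta())
  validate_parameters(params)
  params
}

#' Validate a parameter set
#'
#' Checks that probabilities and utilities lie in \[0, 1\], costs are
#' non-negative, cycle counts are positive integers, and the competing risks
#' leaving the hypertension state sum to at most 1 for every risk profile.
#'
#' @param params A `pa_parameters` object.
#' @return The validated object, invisibly.
#' @export
validate_parameters <- function(params) {
  meta <- attr(params, "meta")
  missing <- setdiff(meta$id, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  for (id in meta$id) {
    v <- params[[id]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", id, "' must be a single finite number")
    cat_ <- meta$category[meta$id == id]
    if (cat_ %in% c("tree_probability", "transition_probability", "utility") &&
        (v < 0 || v > 1))
      stop("parameter '", id, "' is a ", cat_, " and must lie in [0, 1], got ", v)
    if (cat_ %in% c("cost_initial", "cost_annual") && v < 0)
      stop("parameter '", id, "' is a cost and must be non-negative, got ", v)
    if (cat_ == "cycles" && (v < 1 || v != round(v)))
      stop("parameter '", id, "' must be a positive whole number of years, got ", v)
    if (cat_ == "discount" && (v < 0 || v >= 1))
      stop("discount rate must lie in [0, 1), got ", v)
  }
  for (profile in c("cured", "pa", "eht")) {
    s <- params[[paste0(profile, "_death")]] + params[[paste0(profile, "_hf")]] +
      params[[paste0(profile, "_stroke")]]
    if (s > 1)
      stop("competing annual risks for profile '", profile,
           "' sum to ", signif(s, 4), " > 1")
  }
  invisible(params)
}

#' Read a parameter file
#'
#' Reads a YAML file containing a top-level `parameters` mapping of parameter
#' id to value. Parameters not present in the file fall back to
#' [default_parameters()]. The result is validated before it is returned.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated `pa_parameters` object.
#' @seealso [save_parameters()] for the inverse operation.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- yaml::read_yaml(path)
  vals <- if (!is.null(doc$parameters)) doc$parameters else doc
  if (!is.list(vals) || is.null(names(vals)) || any(names(vals) == ""))
    stop("parameter file must contain a named mapping of parameter values")
  default_parameters(overrides = vals)
}

#' Write a parameter file
#'
#' @param params A `pa_parameters` object.
#' @param path Output path; written as YAML with a top-level `parameters` key.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  validate_parameters(params)
  vals <- unclass(params)
  attr(vals, "meta") <- NULL
  yaml::write_yaml(list(parameters = vals), path)
  invisible(path)
}

#' Deterministic sensitivity range of a parameter
#'
#' One-way sensitivity ranges follow the published deviations: costs are
#' varied by +/-20%, utilities by +/-8% and probabilities by +/-30% (clamped
#' to \[0, 1\]); the discount rate is swept over 0-4%. Cycle counts have no
#' deterministic range (they are swept separately, see [cycle_sweep()]).
#'
#' @param params A `pa_parameters` object.
#' @param id Parameter id.
#' @return Numeric vector `c(low, high)` bracketing the point estimate.
#' @export
dsa_range <- function(params, id) {
  meta <- attr(params, "meta")
  if (!id %in% meta$id) stop("unknown parameter id: ", id)
  v <- params[[id]]
  cat_ <- meta$category[meta$id == id]
  r <- switch(cat_,
    cost_initial = ,
    cost_annual = c(v * 0.8, v * 1.2),
    utility = pmin(pmax(c(v * 0.92, v * 1.08), 0), 1),
    tree_probability = ,
    transition_probability = pmin(pmax(c(v * 0.7, v * 1.3), 0), 1),
    discount = c(0, 0.04),
    cycles = c(v, v)
  )
  stats::setNames(r, c("low", "high"))
}

#' Resolved parameter table
#'
#' @param params A `pa_parameters` object.
#' @return A data frame with one row per parameter: id, value, units,
#'   category, deterministic range and probabilistic sensitivity family,
#'   suitable for CSV export with [utils::write.csv()].
#' @export
parameter_table <- function(params) {
  meta <- attr(params, "meta")
  rng <- t(vapply(meta$id, function(id) dsa_range(params, id), numeric(2)))
  data.frame(
    id = meta$id,
    value = unlist(params[meta$id], use.names = FALSE),
    units = meta$units,
    category = meta$category,
    dsa_low = rng[, 1],
    dsa_high = rng[, 2],
    psa_family = meta$psa_family,
    row.names = NULL
  )
}

#' @export
print.pa_parameters <- function(x, ...) {
  cat("Primary aldosteronism cost-effectiveness parameter set\n")
  tab <- parameter_table(x)
  print(tab, row.names = FALSE, digits = 6)
  invisible(x)
}
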