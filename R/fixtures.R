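## Default model inputs: the published parameter, resource-use, unit-cost and
## utility values for unilateral cochlear implantation in UK adults, 2018 GBP.

#' Default model parameter set
#'
#' All structural and probabilistic inputs: cohort age, discount rate,
#' eligibility, device failure and discontinuation probabilities, hearing-aid
#' lifetime and compliance, sound-processor upgrade timing, health-state
#' utilities, adverse-event probabilities and disutilities, and per-block
#' cost multipliers. Where the source reports a 95\% CI it is used verbatim;
#' the remaining probabilistic parameters carry an assumed interval of
#' +/-20\% around the mean (flagged `ci_assumed`), and the per-block cost
#' multipliers (mean 1) likewise. Structural constants are `fixed`.
#'
#' @return An unfitted `uci_parameter_set`.
#' @export
default_parameter_set <- function() {
  # assumed +/-20% interval, kept decimal-clean so the CSV fixture
  # round-trips exactly
  pm20 <- function(m) round(c(0.8 * m, 1.2 * m), 10)
  p <- function(name, mean, lo = NA, hi = NA, family = "fixed", units = "",
                assumed = FALSE)
    parameter_spec(name, mean, lo, hi, family, units, ci_assumed = assumed)
  ass <- function(name, mean, family, units)
    p(name, mean, pm20(mean)[1], pm20(mean)[2], family, units, assumed = TRUE)
  parameter_set(
    p("average_age", 52.8, units = "years"),
    p("discount_rate", 0.035, units = "per year"),
    p("prop_eligible", 0.70, 0.372, 0.938, "beta", "proportion"),
    p("p_internal_failure", 0.025, 0.011, 0.040, "beta", "probability"),
    p("p_external_failure", 0.004, 0.002, 0.018, "beta", "probability"),
    p("p_discontinue", 0.077, 0.009, 0.206, "beta", "probability"),
    p("prop_benefit_ha", 0.50, 0.061, 0.939, "beta", "proportion"),
    p("ha_lifetime_years", 5, 1.3, 11, "gamma", "years"),
    p("upgrade_time_months", 106, 29, 232, "gamma", "months"),
    p("p_ha_compliant", 0.50, 0.061, 0.939, "beta", "proportion"),
    ## Health-state utilities and increments
    ass("u_base_traditional", 0.410, "beta", "utility"),
    ass("u_base_marginal", 0.494, "beta", "utility"),
    ass("u_gain_traditional", 0.214, "beta", "utility"),
    ass("u_gain_marginal", 0.151, "beta", "utility"),
    ## Norm decrements are structural (they define the norm anchor)
    p("norm_decrement_traditional", 0.439, units = "utility"),
    p("norm_decrement_marginal", 0.374, units = "utility"),
    ## Adverse-event disutilities (six-month events unless long-term)
    ass("du_dysgeusia", 0.020, "beta", "utility"),
    ass("du_st_vertigo", 0.033, "beta", "utility"),
    ass("du_tinnitus", 0.050, "beta", "utility"),
    ass("du_infection", 0.042, "beta", "utility"),
    ass("du_lt_vertigo", 0.033, "beta", "utility"),
    ## Adverse-event probabilities (per implantation surgery)
    ass("p_dysgeusia", 0.065, "beta", "probability"),
    ass("p_st_vertigo", 0.194, "beta", "probability"),
    ass("p_infection", 0.015, "beta", "probability"),
    ass("p_tinnitus", 0.036, "beta", "probability"),
    ass("p_lt_vertigo", 0.014, "beta", "probability"),
    ## Cost-block multipliers (mean 1): scale each resource block in the PSA
    ass("c_assessment", 1, "gamma", "multiplier"),
    ass("c_surgery_device", 1, "gamma", "multiplier"),
    ass("c_hearing_aid", 1, "gamma", "multiplier"),
    ass("c_year1", 1, "gamma", "multiplier"),
    ass("c_maintenance", 1, "gamma", "multiplier"),
    ass("c_processor", 1, "gamma", "multiplier"),
    ass("c_explant", 1, "gamma", "multiplier"),
    ass("c_reimplant", 1, "gamma", "multiplier"),
    ass("c_adverse_event", 1, "gamma", "multiplier")
  )
}

#' Default resource-use and unit-cost tables (2018 GBP)
#'
#' One row per resource item, grouped into blocks: pre-implant assessment,
#' surgery (device + theatre), hearing aids, year-1 programming and
#' rehabilitation, year-2+ maintenance, sound-processor replacement/upgrade,
#' explant, re-implant, and short-/long-term adverse events. Item cost is
#' `n_visits * units_per_visit * unit_cost`.
#'
#' @return data.frame with columns `block`, `label`, `n_visits`,
#'   `units_per_visit`, `unit_cost`; class `uci_cost_tables`.
#' @export
default_cost_tables <- function() {
  r <- function(block, label, n_visits, units, unit_cost)
    data.frame(block = block, label = label, n_visits = n_visits,
               units_per_visit = units, unit_cost = unit_cost,
               stringsAsFactors = FALSE)
  tab <- rbind(
    ## Pre-implant assessment (referral through pre-procedural discussion)
    r("assessment", "referral_audiologist",            1, 1,   84),
    r("assessment", "removing_earwax",                 1, 1,   106),
    r("assessment", "initial_assessment_audiologist",  1, 1.5, 84),
    r("assessment", "initial_assessment_slt",          1, 1.5, 96),
    r("assessment", "vestibular_assessment",           1, 1.5, 86),
    r("assessment", "radiologist",                     1, 1,   74),
    r("assessment", "mri_scan",                        1, 1,   138),
    r("assessment", "ct_scan",                         1, 1,   88),
    r("assessment", "audioscientist",                  1, 1,   84),
    r("assessment", "electrophysiology_assessment",    1, 1,   70),
    r("assessment", "preop_audiologist",               1, 1.5, 84),
    r("assessment", "ent_surgeon_consultation",        1, 1,   104),
    r("assessment", "anaesthetist_consultation",       1, 1,   130),
    r("assessment", "multidisciplinary_team_meeting",  1, 1,   284),
    r("assessment", "gp_meningitis_consultation",      1, 1,   31),
    r("assessment", "meningitis_vaccination",          1, 1,   60),
    r("assessment", "surgery_coordinator",             1, 1,   44),
    ## Implant surgery
    r("surgery", "uci_operation_surgical",             1, 1,   5956),
    r("surgery", "uci_operation_device",               1, 1,   16964),
    ## Hearing aids
    r("hearing_aid", "one_hearing_aid",                1, 1,   166),
    r("hearing_aid", "pair_of_hearing_aids",           1, 1,   332),
    ## Device programming and rehabilitation, year 1
    r("year1", "gp_medical_check",                     1, 1,   31),
    r("year1", "programming_audiologist",              6, 1.5, 84),
    r("year1", "aural_training_slt",                   4.5, 1.5, 96),
    ## Follow-up care, year 2 and beyond (annual quantities)
    r("maintenance", "tuning_audiologist",             1, 1,   84),
    r("maintenance", "tuning_slt",                     1, 1,   96),
    r("maintenance", "equipment_maintenance",          1, 1,   328),
    r("maintenance", "annual_administration",          1, 1,   44),
    ## Sound processor replacement / upgrade
    r("processor", "external_component",               1, 1,   5000),
    r("processor", "tuning_audiologist",               1, 1.5, 84),
    r("processor", "tuning_slt",                       1, 1.5, 96),
    ## Explant
    r("explant", "assessment_audiologist",             1, 1.5, 84),
    r("explant", "explant_operation",                  1, 1,   4253),
    ## Re-implant
    r("reimplant", "preop_audiologist",                1, 1.5, 84),
    r("reimplant", "ent_surgeon_consultation",         1, 1,   104),
    r("reimplant", "anaesthetist_consultation",        1, 1,   130),
    r("reimplant", "multidisciplinary_team_meeting",   1, 1,   284),
    r("reimplant", "surgery_coordinator",              1, 1,   44),
    r("reimplant", "uci_operation_surgical",           1, 1,   5956),
    r("reimplant", "gp_medical_check",                 1, 1,   31),
    ## Short-term adverse events (cost per event)
    r("ae_short_term", "dysgeusia_gp_visit",           1, 1,   31),
    r("ae_short_term", "vertigo_gp_visit",             1, 1,   31),
    r("ae_short_term", "tinnitus_gp_visit",            1, 1,   31),
    r("ae_short_term", "infection_gp_visit",           1, 1,   31),
    r("ae_short_term", "infection_antibiotics",        1, 1,   10),
    ## Long-term adverse events (annual cost while in the state)
    r("ae_long_term", "vertigo_gp_visit",              1, 1,   31)
  )
  class(tab) <- c("uci_cost_tables", "data.frame")
  tab
}

#' Default utility / disutility / adverse-event probability table
#'
#' Baseline health-state utilities by candidate type (traditional: no
#' pre-implant hearing-aid benefit; marginal: some benefit), implant utility
#' increments, the population-norm decrements used to anchor the ageing
#' curve, and the adverse-event probabilities and disutilities.
#'
#' @return A named list with components `baseline`, `decrement`,
#'   `uci_increment` (each named by candidate type), `st_disutility`,
#'   `st_ae_prob`, `lt_disutility`, `lt_ae_prob` (named by event);
#'   class `uci_utility_table`.
#' @export
default_utility_table <- function() {
  structure(list(
    baseline      = c(traditional = 0.410, marginal = 0.494),
    decrement     = c(traditional = 0.439, marginal = 0.374),
    uci_increment = c(traditional = 0.214, marginal = 0.151),
    st_disutility = c(dysgeusia = 0.020, vertigo = 0.033, tinnitus = 0.050,
                      wound_infection = 0.042),
    st_ae_prob    = c(dysgeusia = 0.065, vertigo = 0.194, tinnitus = 0.036,
                      wound_infection = 0.015),
    lt_disutility = c(vertigo = 0.033),
    lt_ae_prob    = c(vertigo = 0.014)
  ), class = "uci_utility_table")
}

#' Build a utility table from a parameter draw
#'
#' Maps the utility-related entries of a [sample_draw()] onto the
#' `uci_utility_table` layout, so probabilistic runs vary utilities and
#' adverse-event inputs coherently with everything else.
#'
#' @param draw A `uci_parameter_draw`.
#' @return A `uci_utility_table`.
#' @export
utility_table_from_draw <- function(draw) {
  structure(list(
    baseline      = c(traditional = draw$u_base_traditional,
                      marginal = draw$u_base_marginal),
    decrement     = c(traditional = draw$norm_decrement_traditional,
                      marginal = draw$norm_decrement_marginal),
    uci_increment = c(traditional = draw$u_gain_traditional,
                      marginal = draw$u_gain_marginal),
    st_disutility = c(dysgeusia = draw$du_dysgeusia,
                      vertigo = draw$du_st_vertigo,
                      tinnitus = draw$du_tinnitus,
                      wound_infection = draw$du_infection),
    st_ae_prob    = c(dysgeusia = draw$p_dysgeusia,
                      vertigo = draw$p_st_vertigo,
                      tinnitus = draw$p_tinnitus,
                      wound_infection = draw$p_infection),
    lt_disutility = c(vertigo = draw$du_lt_vertigo),
    lt_ae_prob    = c(vertigo = draw$p_lt_vertigo)
  ), class = "uci_utility_table")
}

#' Read / write the resource-use tables as CSV
#'
#' @param tables A `uci_cost_tables` data.frame.
#' @param path File path.
#' @export
write_cost_tables <- function(tables, path) {
  utils::write.csv(as.data.frame(tables), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' @rdname write_cost_tables
#' @export
read_cost_tables <- function(path) {
  if (!file.exists(path))
    stop("cost table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "label", "n_visits", "units_per_visit", "unit_cost")
  if (!all(need %in% names(df)))
    stop("cost table ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  for (col in c("n_visits", "units_per_visit", "unit_cost"))
    df[[col]] <- as.numeric(df[[col]])
  class(df) <- c("uci_cost_tables", "data.frame")
  df
}

#' Write the full default input bundle to a directory
#'
#' Emits `parameters.csv`, `costs.csv`, `life_table.csv` and
#' `norm_curve_<type>.csv` so a run can be reproduced from plain files.
#'
#' @param dir Output directory (created if needed).
#' @param life_table,norm_traditional,norm_marginal Optional overrides.
#' @return The directory path, invisibly.
#' @export
write_model_inputs <- function(dir, life_table = make_life_table(),
                               norm_traditional = make_norm_curve(52.8, 0.849),
                               norm_marginal = make_norm_curve(52.8, 0.868)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_parameter_set(default_parameter_set(),
                      file.path(dir, "parameters.csv"))
  write_cost_tables(default_cost_tables(), file.path(dir, "costs.csv"))
  write_life_table(life_table, file.path(dir, "life_table.csv"))
  write_norm_curve(norm_traditional,
                   file.path(dir, "norm_curve_traditional.csv"))
  write_norm_curve(norm_marginal, file.path(dir, "norm_curve_marginal.csv"))
  invisible(dir)
}
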