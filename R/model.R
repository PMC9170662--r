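#' Assemble a cochlear-implant cost-utility model
#'
#' Bundles everything one evaluation needs: the parameter set (fitted on
#' construction), the resource-use tables, a life table, the candidate-type
#' population utility-norm curves, and the run configuration. The two
#' evaluation scenarios compare a unilateral cochlear implant (UCI) against
#' a hearing aid (marginal candidates, who had some benefit from aids) or
#' against no hearing aid (traditional candidates, who had none); each
#' scenario yields its own ICER.
#'
#' @param params A `uci_parameter_set`; fitted here if not already.
#' @param cost_tables A `uci_cost_tables` data.frame.
#' @param life_table A `uci_life_table`.
#' @param norm_decline Population utility-norm decline per decade of age.
#'   The norm curves are anchored at the start age to baseline utility +
#'   reported norm decrement for each candidate type.
#' @param config A `uci_config`.
#' @return A `uci_model` object.
#' @examples
#' mod <- uci_model()
#' bc <- base_case(mod, "vs_noHA")
#' bc
#' @export
uci_model <- function(params = default_parameter_set(),
                      cost_tables = default_cost_tables(),
                      life_table = make_life_table(),
                      norm_decline = 0.03,
                      config = model_config()) {
  if (!isTRUE(attr(params, "fitted"))) params <- fit_parameter_set(params)
  ut <- default_utility_table()
  norms <- list(
    traditional = make_norm_curve(config$start_age,
                                  ut$baseline[["traditional"]] +
                                    ut$decrement[["traditional"]],
                                  norm_decline),
    marginal = make_norm_curve(config$start_age,
                               ut$baseline[["marginal"]] +
                                 ut$decrement[["marginal"]],
                               norm_decline)
  )
  ## gamma shapes for the renewal clocks come from the fitted parameter set
  ## (fitted from the row's CI when the prior itself is held fixed)
  renewal_shape <- function(name) {
    row <- params[name, ]
    if (!is.na(row$par1) && row$family == "gamma") return(row$par1)
    unname(fit_gamma_from_mean_ci(row$mean, row$ci_low, row$ci_high,
                                  name = name)[1L])
  }
  config$upgrade_time_shape <- renewal_shape("upgrade_time_months")
  config$ha_lifetime_shape <- renewal_shape("ha_lifetime_years")
  structure(list(params = params, cost_tables = cost_tables,
                 life_table = life_table, norms = norms,
                 norm_decline = norm_decline, config = config),
            class = "uci_model")
}

.scenario_parts <- function(scenario = c("vs_noHA", "vs_HA")) {
  scenario <- match.arg(scenario)
  if (scenario == "vs_HA") {
    list(scenario = scenario, candidate = "marginal", comparator = "HA")
  } else {
    list(scenario = scenario, candidate = "traditional", comparator = "no_HA")
  }
}

## Run both arms of a scenario for one draw; shared by the base case and PSA.
.evaluate_draw <- function(model, draw, scenario, config = model$config) {
  sc <- .scenario_parts(scenario)
  utable <- utility_table_from_draw(draw)
  schedule <- build_cost_schedule(model$cost_tables, draw)
  norm <- model$norms[[sc$candidate]]
  renewals <- .draw_renewals(draw, config)
  uci <- run_cohort("UCI", sc$candidate, draw, model$life_table, norm,
                    schedule, utable, config, renewals)
  cmp <- run_cohort(sc$comparator, sc$candidate, draw, model$life_table,
                    norm, schedule, utable, config, renewals)
  list(uci = uci, comparator = cmp, icer = compute_icer(uci, cmp))
}

#' Deterministic base-case evaluation of one scenario
#'
#' Every parameter at its mean; both arms run to the horizon; incremental
#' cost, QALYs and the ICER reported.
#'
#' @param model A `uci_model`.
#' @param scenario `"vs_noHA"` (traditional candidates) or `"vs_HA"`
#'   (marginal candidates).
#' @param config Optional `uci_config` override.
#' @return A `uci_base_case` object.
#' @export
base_case <- function(model, scenario = c("vs_noHA", "vs_HA"),
                      config = model$config) {
  scenario <- match.arg(scenario)
  res <- .evaluate_draw(model, mean_draw(model$params), scenario, config)
  structure(c(res, list(scenario = scenario)), class = "uci_base_case")
}

#' @export
print.uci_base_case <- function(x, ...) {
  sc <- .scenario_parts(x$scenario)
  cat(sprintf("Base case, %s (%s candidates)\n", x$scenario, sc$candidate))
  cat(sprintf("  %-28s cost %9.0f  QALY %6.2f\n", x$comparator$arm,
              x$comparator$discounted_cost, x$comparator$discounted_qaly))
  cat(sprintf("  %-28s cost %9.0f  QALY %6.2f\n", "Unilateral cochlear implant",
              x$uci$discounted_cost, x$uci$discounted_qaly))
  cat(sprintf("  %-28s cost %9.0f  QALY %6.2f\n", "Difference",
              x$icer$delta_cost, x$icer$delta_qaly))
  if (x$icer$dominance == "none") {
    cat(sprintf("  ICER: %.0f GBP per QALY gained\n", x$icer$icer))
  } else cat("  ICER not reported:", x$icer$dominance, "\n")
  invisible(x)
}

#' @export
print.uci_model <- function(x, ...) {
  cat("Cochlear-implant cost-utility model\n")
  cat(sprintf("  %d parameters (%d with fitted priors)\n", nrow(x$params),
              sum(x$params$family != "fixed")))
  cat(sprintf("  start age %.1f, horizon age %.0f, %.1f%% discount, 6-month cycles\n",
              x$config$start_age, x$config$horizon_age,
              100 * x$config$discount_rate))
  cat(sprintf("  life table: ages %d-%d; norm decline %.3f utility/decade\n",
              min(x$life_table$age), max(x$life_table$age), x$norm_decline))
  invisible(x)
}

#' @export
summary.uci_model <- function(object, ...) {
  bc1 <- base_case(object, "vs_noHA")
  bc2 <- base_case(object, "vs_HA")
  out <- data.frame(
    scenario = c("vs_noHA", "vs_HA"),
    candidate = c("traditional", "marginal"),
    uci_cost = c(bc1$uci$discounted_cost, bc2$uci$discounted_cost),
    uci_qaly = c(bc1$uci$discounted_qaly, bc2$uci$discounted_qaly),
    comparator_cost = c(bc1$comparator$discounted_cost,
                        bc2$comparator$discounted_cost),
    comparator_qaly = c(bc1$comparator$discounted_qaly,
                        bc2$comparator$discounted_qaly),
    delta_cost = c(bc1$icer$delta_cost, bc2$icer$delta_cost),
    delta_qaly = c(bc1$icer$delta_qaly, bc2$icer$delta_qaly),
    icer = c(bc1$icer$icer, bc2$icer$icer))
  class(out) <- c("summary.uci_model", "data.frame")
  out
}

#' @export
print.summary.uci_model <- function(x, ...) {
  cat("Deterministic base case, both scenarios:\n")
  print.data.frame(cbind(x[1:2], round(x[3:9], 2)), row.names = FALSE)
  invisible(x)
}
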