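#' Hash of the model-relevant configuration
#'
#' FNV-1a style 32-bit hash over the serialized configuration, so two runs
#' share a hash exactly when every model-relevant field matches.
#'
#' @param config A `uci_config` (or any list of scalars).
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  txt <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1L)),
    sep = "=", collapse = ";")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.run_metadata <- function(model, seed = NA_integer_) {
  list(seed = seed, config_hash = config_hash(model$config),
       package_version = as.character(utils::packageVersion("cochleaCEA")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write base-case results as JSON (with run metadata)
#'
#' @param bc A `uci_base_case`.
#' @param model The `uci_model` it came from.
#' @param path Output JSON path.
#' @export
write_base_case <- function(bc, model, path) {
  out <- list(
    scenario = bc$scenario,
    uci = list(cost = bc$uci$discounted_cost,
               qaly = bc$uci$discounted_qaly),
    comparator = list(arm = bc$comparator$arm,
                      cost = bc$comparator$discounted_cost,
                      qaly = bc$comparator$discounted_qaly),
    difference = list(cost = bc$icer$delta_cost, qaly = bc$icer$delta_qaly,
                      icer = bc$icer$icer, dominance = bc$icer$dominance),
    metadata = .run_metadata(model))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write PSA summary as JSON (with run metadata)
#'
#' @param psa A `uci_psa`.
#' @param model The `uci_model` it came from.
#' @param path Output JSON path.
#' @export
write_psa_summary <- function(psa, model, path) {
  out <- list(
    scenario = psa$scenario, n = psa$n,
    mean_dcost = psa$mean_dcost, mean_dqaly = psa$mean_dqaly,
    icer_ratio_of_means = psa$icer_ratio_of_means,
    icer_mean_of_ratios = psa$icer_mean_of_ratios,
    ci_dcost = psa$ci_dcost, ci_dqaly = psa$ci_dqaly, ci_icer = psa$ci_icer,
    prob_ce_20000 = prob_cost_effective(psa, 20000),
    n_resampled = psa$n_resampled,
    metadata = .run_metadata(model, psa$seed))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
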