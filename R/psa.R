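#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the fitted priors (common random numbers
#' across both arms within each draw), runs the cohort model for each, and
#' collects the per-draw incremental cost/QALY pairs. Draws whose transition
#' structure fails validation are logged and resampled from fresh substreams.
#'
#' @param model A `uci_model`.
#' @param n Number of Monte Carlo draws.
#' @param seed Root integer seed; results are bit-reproducible for a fixed
#'   `(seed, n)` and draw `k` does not depend on draws `1..k-1`.
#' @param scenario `"vs_noHA"` or `"vs_HA"`.
#' @param thresholds Willingness-to-pay grid (GBP/QALY) for the CEAC.
#' @return A `uci_psa` object: per-draw results (`draws`), summary
#'   statistics, and the CEAC.
#' @export
run_psa <- function(model, n = 10000L, seed = 1L,
                    scenario = c("vs_noHA", "vs_HA"),
                    thresholds = seq(0, 50000, by = 500)) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 1L)
  dcost <- numeric(n)
  dqaly <- numeric(n)
  ucost <- numeric(n)
  uqaly <- numeric(n)
  resampled <- integer(0)
  for (k in seq_len(n)) {
    draw_id <- k
    repeat {
      res <- tryCatch(
        .evaluate_draw(model, sample_draw(model$params, draw_id, seed),
                       scenario),
        error = function(e) e)
      if (!inherits(res, "error")) break
      resampled <- c(resampled, draw_id)
      draw_id <- draw_id + n  # fresh substream, still keyed to (seed, k)
      if (draw_id > 100L * n)
        stop("PSA draw ", k, " repeatedly invalid: ",
             conditionMessage(res), call. = FALSE)
    }
    dcost[k] <- res$icer$delta_cost
    dqaly[k] <- res$icer$delta_qaly
    ucost[k] <- res$uci$discounted_cost
    uqaly[k] <- res$uci$discounted_qaly
  }
  draws <- data.frame(draw_id = seq_len(n), dcost = dcost, dqaly = dqaly,
                      uci_cost = ucost, uci_qaly = uqaly,
                      icer = ifelse(dqaly != 0, dcost / dqaly, NA_real_))
  curve <- ceac(draws, thresholds)
  q <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                   na.rm = TRUE)
  structure(list(
    scenario = scenario, n = n, seed = seed, draws = draws,
    mean_dcost = mean(dcost), mean_dqaly = mean(dqaly),
    icer_ratio_of_means = mean(dcost) / mean(dqaly),
    icer_mean_of_ratios = mean(draws$icer, na.rm = TRUE),
    ci_dcost = q(dcost), ci_dqaly = q(dqaly), ci_icer = q(draws$icer),
    ceac = curve, n_resampled = length(resampled),
    resampled_draws = resampled), class = "uci_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' `CEAC(lambda)` is the share of draws with non-negative net monetary
#' benefit `lambda * dQALY - dcost`; the net-benefit rule handles all
#' quadrants of the cost-effectiveness plane.
#'
#' @param draws data.frame with columns `dcost`, `dqaly` (e.g.
#'   `uci_psa$draws`).
#' @param thresholds Willingness-to-pay values (GBP/QALY).
#' @return data.frame with columns `threshold`, `probability`.
#' @export
ceac <- function(draws, thresholds = seq(0, 50000, by = 500)) {
  stopifnot(nrow(draws) > 0L)
  prob <- vapply(thresholds, function(wtp)
    mean(wtp * draws$dqaly - draws$dcost >= 0), numeric(1L))
  data.frame(threshold = thresholds, probability = prob)
}

#' Probability cost-effective at a threshold
#'
#' @param psa A `uci_psa`.
#' @param wtp Willingness to pay (GBP/QALY).
#' @return Probability in [0, 1].
#' @export
prob_cost_effective <- function(psa, wtp = 20000) {
  ceac(psa$draws, wtp)$probability
}

#' @export
print.uci_psa <- function(x, ...) {
  cat(sprintf("PSA, %s: %d draws (seed %d%s)\n", x$scenario, x$n, x$seed,
              if (x$n_resampled) paste0(", ", x$n_resampled, " resampled")
              else ""))
  cat(sprintf("  mean difference: cost %.0f GBP, %.3f QALYs\n",
              x$mean_dcost, x$mean_dqaly))
  cat(sprintf("  ICER (ratio of means) %.0f, (mean of ratios) %.0f GBP/QALY\n",
              x$icer_ratio_of_means, x$icer_mean_of_ratios))
  cat(sprintf("  95%% intervals: cost (%.0f, %.0f), QALY (%.3f, %.3f), ICER (%.0f, %.0f)\n",
              x$ci_dcost[1], x$ci_dcost[2], x$ci_dqaly[1], x$ci_dqaly[2],
              x$ci_icer[1], x$ci_icer[2]))
  cat(sprintf("  P(cost-effective at 20000 GBP/QALY) = %.3f\n",
              prob_cost_effective(x)))
  invisible(x)
}

#' Plot a PSA: cost-effectiveness plane or acceptability curve
#'
#' @param x A `uci_psa`.
#' @param type `"plane"` (incremental cost vs QALY scatter) or `"ceac"`.
#' @param wtp Threshold line drawn on the plane (GBP/QALY).
#' @param ... Passed to the base plotting calls.
#' @export
plot.uci_psa <- function(x, type = c("plane", "ceac"), wtp = 20000, ...) {
  type <- match.arg(type)
  if (type == "plane") {
    graphics::plot(x$draws$dqaly, x$draws$dcost, pch = 16, cex = 0.3,
                   col = grDevices::adjustcolor("steelblue", 0.5),
                   xlab = "Incremental QALYs",
                   ylab = "Incremental cost (GBP)",
                   main = paste("Cost-effectiveness plane,", x$scenario), ...)
    graphics::abline(0, wtp, lty = 2)
    graphics::abline(h = 0, v = 0, col = "grey60")
  } else {
    graphics::plot(x$ceac$threshold, x$ceac$probability, type = "l",
                   ylim = c(0, 1), xlab = "Willingness to pay (GBP/QALY)",
                   ylab = "Probability cost-effective",
                   main = paste("CEAC,", x$scenario), ...)
    graphics::abline(v = wtp, lty = 2)
  }
  invisible(x)
}

#' Write PSA draws and CEAC as CSV
#'
#' @param psa A `uci_psa`.
#' @param draws_path,ceac_path Output paths (`NULL` to skip either).
#' @export
write_psa <- function(psa, draws_path = NULL, ceac_path = NULL) {
  if (!is.null(draws_path))
    utils::write.csv(psa$draws[c("draw_id", "dcost", "dqaly")], draws_path,
                     row.names = FALSE)
  if (!is.null(ceac_path))
    utils::write.csv(psa$ceac, ceac_path, row.names = FALSE)
  invisible(psa)
}

#' One-way deterministic sensitivity of the ICER to one parameter
#'
#' Runs the base case twice with the parameter pinned at `low` and `high`
#' (everything else at its mean) and reports the two ICERs. The discount
#' rate is addressed as `"discount_rate"`.
#'
#' @param model A `uci_model`.
#' @param parameter Parameter name (a row of the parameter set, or
#'   `"discount_rate"`).
#' @param low,high Pin values; defaults are the parameter's 95\% CI limits.
#' @param scenario `"vs_noHA"` or `"vs_HA"`.
#' @return A `uci_tornado_entry`: one-row data.frame with the pinned values,
#'   the ICER at each, and the spread.
#' @export
one_way <- function(model, parameter, low = NULL, high = NULL,
                    scenario = c("vs_noHA", "vs_HA")) {
  scenario <- match.arg(scenario)
  ps <- model$params
  if (!(parameter %in% ps$name))
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  row <- ps[parameter, ]
  if (is.null(low)) low <- row$ci_low
  if (is.null(high)) high <- row$ci_high
  if (is.na(low) || is.na(high))
    stop("parameter '", parameter, "' has no range: give low/high",
         call. = FALSE)
  if (row$family == "beta" && (low < 0 || high > 1))
    stop("pin values for '", parameter, "' outside [0,1]", call. = FALSE)
  if (row$family == "gamma" && low <= 0)
    stop("pin values for '", parameter, "' must be positive", call. = FALSE)
  run_at <- function(value) {
    draw <- mean_draw(model$params)
    config <- model$config
    if (parameter == "discount_rate") {
      config$discount_rate <- value
    } else draw[[parameter]] <- value
    .evaluate_draw(model, draw, scenario, config)$icer$icer
  }
  out <- data.frame(parameter = parameter, low = low, high = high,
                    icer_low = run_at(low), icer_high = run_at(high))
  out$spread <- abs(out$icer_high - out$icer_low)
  class(out) <- c("uci_tornado_entry", "data.frame")
  out
}

#' Tornado (one-way) sensitivity analysis over a set of parameters
#'
#' @param model A `uci_model`.
#' @param parameters Parameter names; default: every parameter with a CI.
#' @param scenario `"vs_noHA"` or `"vs_HA"`.
#' @return A `uci_tornado` data.frame sorted by decreasing ICER spread, with
#'   the base-case ICER as attribute `base_icer`.
#' @export
tornado <- function(model, parameters = NULL,
                    scenario = c("vs_noHA", "vs_HA")) {
  scenario <- match.arg(scenario)
  if (is.null(parameters))
    parameters <- model$params$name[!is.na(model$params$ci_low)]
  entries <- do.call(rbind, lapply(parameters, function(p)
    as.data.frame(one_way(model, p, scenario = scenario))))
  entries <- entries[order(-entries$spread), ]
  rownames(entries) <- NULL
  attr(entries, "base_icer") <- base_case(model, scenario)$icer$icer
  class(entries) <- c("uci_tornado", "data.frame")
  entries
}

#' @export
print.uci_tornado <- function(x, ...) {
  cat(sprintf("Tornado analysis (base-case ICER %.0f GBP/QALY):\n",
              attr(x, "base_icer")))
  print.data.frame(cbind(x["parameter"], round(x[-1], 1)),
                   row.names = FALSE)
  invisible(x)
}

#' Plot a tornado diagram
#'
#' @param x A `uci_tornado`.
#' @param top Number of parameters shown (largest spreads first).
#' @param ... Passed to `graphics::barplot`-style calls.
#' @export
plot.uci_tornado <- function(x, top = 10L, ...) {
  x <- utils::head(x, top)
  base <- attr(x, "base_icer")
  n <- nrow(x)
  graphics::plot(NULL, xlim = range(c(x$icer_low, x$icer_high, base)),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "ICER (GBP/QALY)", ylab = "",
                 main = "One-way sensitivity", ...)
  graphics::axis(2, at = n:1, labels = x$parameter, las = 1, cex.axis = 0.7)
  for (i in seq_len(n))
    graphics::rect(min(x$icer_low[i], x$icer_high[i]), n - i + 0.7,
                   max(x$icer_low[i], x$icer_high[i]), n - i + 1.3,
                   col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Discount-rate scenario sweep
#'
#' @param model A `uci_model`.
#' @param rates Annual discount rates to evaluate.
#' @param scenario `"vs_noHA"` or `"vs_HA"`.
#' @return data.frame with one row per rate: costs, QALYs, ICER.
#' @export
discount_scenarios <- function(model, rates = c(0.015, 0.03, 0.035, 0.05),
                               scenario = c("vs_noHA", "vs_HA")) {
  scenario <- match.arg(scenario)
  do.call(rbind, lapply(rates, function(r) {
    config <- model$config
    config$discount_rate <- r
    bc <- base_case(model, scenario, config = config)
    data.frame(rate = r, uci_qaly = bc$uci$discounted_qaly,
               delta_cost = bc$icer$delta_cost,
               delta_qaly = bc$icer$delta_qaly, icer = bc$icer$icer)
  }))
}

#' Sweep the structural conventions and report each configuration's ICER
#'
#' Evaluates the deterministic base case under every combination of the
#' flagged structural conventions (half-cycle correction, device-failure
#' hazard interpretation, comparator hearing-aid replacement policy), so
#' the sensitivity of results to these open choices is visible at a glance.
#'
#' @param model A `uci_model`.
#' @param scenario `"vs_noHA"` or `"vs_HA"`.
#' @return data.frame: one row per configuration with its incremental cost,
#'   QALYs and ICER.
#' @export
convention_sweep <- function(model, scenario = c("vs_noHA", "vs_HA")) {
  scenario <- match.arg(scenario)
  grid <- expand.grid(half_cycle_correction = c(FALSE, TRUE),
                      failure_interpretation = c("lifetime_cumulative",
                                                 "per_cycle"),
                      ha_replacement = c("compliant", "none", "all"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    config <- model$config
    config$half_cycle_correction <- grid$half_cycle_correction[i]
    config$failure_interpretation <- grid$failure_interpretation[i]
    config$ha_replacement <- grid$ha_replacement[i]
    bc <- base_case(model, scenario, config = config)
    cbind(grid[i, , drop = FALSE],
          data.frame(delta_cost = bc$icer$delta_cost,
                     delta_qaly = bc$icer$delta_qaly, icer = bc$icer$icer))
  }))
  rownames(out) <- NULL
  out
}
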