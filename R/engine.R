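## Markov cohort engine: six-month cycles from implantation (cycle 0) to the
## terminal age, one shared state space for all strategy arms.

#' Health states of the model
#'
#' The implant arm can occupy every state; comparator arms use only the
#' hearing-aid / no hearing-aid / death states. `UCI_st_ae` is a tunnel
#' state occupied for exactly one cycle (short-term adverse events last six
#' months); `death` is absorbing.
#'
#' @return Character vector of state names, in matrix order.
#' @export
model_states <- function() {
  c("UCI_well", "UCI_st_ae", "UCI_lt_ae", "UCI_faulty_nonuser",
    "post_explant_HA_compliant", "post_explant_HA_noncompliant",
    "post_explant_no_HA", "HA_compliant", "HA_noncompliant", "no_HA",
    "death")
}

#' Run configuration
#'
#' Structural conventions of the model that the published account leaves
#' open, each exposed as a flag with the package default.
#'
#' @param horizon_age Terminal age (years); remaining occupancy is forced to
#'   death there.
#' @param cycle_length Cycle length in years; fixed at 0.5 in this model
#'   family.
#' @param discount_rate Annual discount rate for costs and health outcomes.
#' @param start_age Cohort age at implantation.
#' @param half_cycle_correction Apply a half-cycle (trapezoid) correction to
#'   per-cycle accruals. Default `FALSE`.
#' @param failure_interpretation How the internal/external device failure
#'   probabilities are read: `"lifetime_cumulative"` (default; converted to a
#'   constant per-cycle hazard over remaining life expectancy at entry) or
#'   `"per_cycle"`.
#' @param ha_replacement Comparator-arm hearing-aid replacement policy:
#'   `"compliant"` (default; the initial pair for everyone, renewal
#'   replacements for compliant users only), `"none"` (initial pair only) or
#'   `"all"`.
#' @param p_explant_given_discontinue Probability that a patient who
#'   discontinues after an internal failure has the device explanted rather
#'   than keeping it in place unused.
#' @param lt_vertigo_gp_visits_per_year Follow-up GP visits per year in the
#'   long-term vertigo state.
#' @param upgrade_time_shape,ha_lifetime_shape Gamma shape of the
#'   sound-processor upgrade-time and hearing-aid lifetime distributions;
#'   defaults are fitted from the reported 95\% CIs, and probabilistic draws
#'   rescale the gamma scale so its mean tracks the drawn mean.
#' @return A `uci_config` list.
#' @export
model_config <- function(horizon_age = 100, cycle_length = 0.5,
                         discount_rate = 0.035, start_age = 52.8,
                         half_cycle_correction = FALSE,
                         failure_interpretation = c("lifetime_cumulative",
                                                    "per_cycle"),
                         ha_replacement = c("compliant", "none", "all"),
                         p_explant_given_discontinue = 0.5,
                         lt_vertigo_gp_visits_per_year = 1,
                         upgrade_time_shape = NULL,
                         ha_lifetime_shape = NULL) {
  if (!isTRUE(all.equal(cycle_length, 0.5)))
    stop("this model family uses a fixed six-month cycle", call. = FALSE)
  stopifnot(discount_rate >= 0, horizon_age > start_age)
  if (is.null(upgrade_time_shape))
    upgrade_time_shape <- unname(fit_gamma_from_mean_ci(106, 29, 232)[1L])
  if (is.null(ha_lifetime_shape))
    ha_lifetime_shape <- unname(fit_gamma_from_mean_ci(5, 1.3, 11)[1L])
  structure(list(
    horizon_age = horizon_age, cycle_length = cycle_length,
    discount_rate = discount_rate, start_age = start_age,
    half_cycle_correction = half_cycle_correction,
    failure_interpretation = match.arg(failure_interpretation),
    ha_replacement = match.arg(ha_replacement),
    p_explant_given_discontinue = p_explant_given_discontinue,
    lt_vertigo_gp_visits_per_year = lt_vertigo_gp_visits_per_year,
    upgrade_time_shape = upgrade_time_shape,
    ha_lifetime_shape = ha_lifetime_shape), class = "uci_config")
}

#' Per-cycle death probability from an annual life table
#'
#' Converts the annual probability at the containing year of age to a
#' six-month probability: `q_cycle = 1 - (1 - q_annual)^(1/2)`. Ages beyond
#' the table are fatal (`q = 1`).
#'
#' @param life_table A `uci_life_table`.
#' @param age Age in years (vectorized).
#' @return Per-cycle death probability.
#' @export
per_cycle_mortality <- function(life_table, age) {
  1 - (1 - annual_mortality(life_table, age))^(1 / 2)
}

#' Time-dependent event probability from a cumulative survival function
#'
#' `p = 1 - S(t + dt) / S(t)`: the conditional probability that an event on
#' the clock `S` occurs within the next `dt` given none has occurred by `t`.
#' An exhausted clock (`S(t) = 0`) returns 0.
#'
#' @param survival Function of time returning cumulative event-free survival
#'   (non-increasing, `survival(0) = 1`).
#' @param t Time since the clock started.
#' @param dt Cycle length on the same time scale.
#' @return Event probability for the cycle.
#' @export
time_dependent_event_prob <- function(survival, t, dt) {
  s0 <- survival(t)
  ifelse(s0 <= 0, 0, pmin(pmax(1 - survival(t + dt) / s0, 0), 1))
}

#' Discount factor at a cycle index
#'
#' `(1 + rate)^(-cycle / 2)` for six-month cycles; cycle 0 is undiscounted.
#'
#' @param cycle Cycle index (0-based, vectorized).
#' @param annual_rate Annual discount rate, >= 0.
#' @return Discount factor.
#' @export
discount_factor <- function(cycle, annual_rate) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-cycle / 2)
}

## Expected renewal events per six-month cycle for a gamma event clock that
## restarts after every event: the discrete renewal equation u = f + u * f
## solved on a fine internal grid (default one month, midpoint binning, so
## the discrete inter-event mean matches the continuous one) and aggregated
## back to cycles. Agrees with direct simulation of the renewal process to
## about 0.01% of the expected event count.
.renewal_density <- function(n_cycles, mean_months, shape, step = 1) {
  scale <- mean_months / shape
  per_cycle <- as.integer(round(6 / step))
  n_fine <- n_cycles * per_cycle
  s <- stats::pgamma(step * (1:(n_fine + 1L)) - step / 2, shape = shape,
                     scale = scale, lower.tail = FALSE)
  f <- s[-length(s)] - s[-1L]
  f[1L] <- f[1L] + (1 - s[1L])  # sub-half-step mass lumped into the first bin
  u <- numeric(n_fine)
  for (k in seq_len(n_fine)) {
    u[k] <- f[k] + if (k > 1L) sum(u[seq_len(k - 1L)] * f[k - seq_len(k - 1L)])
    else 0
  }
  colSums(matrix(u, nrow = per_cycle))
}

## Renewal densities shared by every arm of one draw (the clocks depend on
## the draw, not the arm).
.draw_renewals <- function(draw, config) {
  t_cycles <- ceiling((config$horizon_age - config$start_age) /
                        config$cycle_length)
  list(up = .renewal_density(t_cycles, draw$upgrade_time_months,
                             config$upgrade_time_shape),
       ha = .renewal_density(t_cycles, draw$ha_lifetime_years * 12,
                             config$ha_lifetime_shape))
}

## Convert a cumulative event probability over remaining lifetime to a
## constant per-cycle hazard.
.per_cycle_hazard <- function(p_lifetime, n_cycles) {
  1 - (1 - p_lifetime)^(1 / n_cycles)
}

## All branch probabilities and derived quantities one run needs; built once
## per (arm, candidate, draw).
.engine_context <- function(arm, candidate, draw, life_table, norm,
                            schedule, utable, config, renewals = NULL) {
  states <- model_states()
  n_s <- length(states)
  t_cycles <- ceiling((config$horizon_age - config$start_age) /
                        config$cycle_length)
  ## interval k (1-based) spans ages [start + (k-1)/2, start + k/2);
  ## mortality is indexed by the interval's starting age, rewards accrue on
  ## the occupancy that arrives at its end
  ages_start <- config$start_age + config$cycle_length * (0:(t_cycles - 1L))
  ages_end <- pmin(ages_start + config$cycle_length, config$horizon_age)
  q <- per_cycle_mortality(life_table, ages_start)

  le_cycles <- max(1L, round(2 * life_expectancy(life_table,
                                                 config$start_age)))
  if (config$failure_interpretation == "lifetime_cumulative") {
    h_int <- .per_cycle_hazard(draw$p_internal_failure, le_cycles)
    h_ext <- .per_cycle_hazard(draw$p_external_failure, le_cycles)
  } else {
    h_int <- draw$p_internal_failure
    h_ext <- draw$p_external_failure
  }

  p_any <- p_st_ae_any(utable)
  p_lt <- unname(utable$lt_ae_prob[["vertigo"]])
  p_disc <- draw$p_discontinue
  p_expl <- config$p_explant_given_discontinue
  p_comp <- draw$p_ha_compliant

  if (is.null(renewals)) renewals <- .draw_renewals(draw, config)
  ev_up <- renewals$up
  ev_ha <- renewals$ha

  ## state-utility matrix: row k = interval k's accrual ages (end of cycle)
  u_mat <- vapply(states, function(s)
    state_utility(s, ages_end, candidate, norm, utable,
                  start_age = config$start_age),
    numeric(t_cycles))

  ## recurring per-cycle costs per state, interval-indexed: year-1 care in
  ## the first two cycles, maintenance from the second year onwards
  c_mat <- matrix(0, t_cycles, n_s, dimnames = list(NULL, states))
  if (arm == "UCI") {
    device <- c("UCI_well", "UCI_st_ae", "UCI_lt_ae")
    yr1 <- seq_len(min(2L, t_cycles))
    c_mat[yr1, device] <- schedule$recurring[["uci_year1_per_cycle"]]
    if (t_cycles > 2L)
      c_mat[-yr1, device] <- schedule$recurring[["uci_maintenance_per_cycle"]]
    c_mat[, "UCI_lt_ae"] <- c_mat[, "UCI_lt_ae"] +
      schedule$recurring[["lt_ae_per_cycle"]] *
        config$lt_vertigo_gp_visits_per_year
  }

  list(arm = arm, candidate = candidate, states = states, n_s = n_s,
       t_cycles = t_cycles, ages_start = ages_start, ages_end = ages_end,
       q = q, h_int = h_int, h_ext = h_ext,
       p_any = p_any, p_lt = p_lt, p_disc = p_disc, p_expl = p_expl,
       p_comp = p_comp, ev_up = ev_up, ev_ha = ev_ha, u_mat = u_mat,
       c_mat = c_mat, schedule = schedule, utable = utable, config = config,
       ## df[k] discounts interval k's rewards and events (time k/2 years)
       df = discount_factor(seq_len(t_cycles), config$discount_rate))
}

## Event-layer transition matrix among living states (death excluded from the
## scaling; rows sum to 1). `first_cycle` carries the surgery adverse-event
## exposure of the implantation cycle.
.event_matrix <- function(ctx, first_cycle) {
  s <- ctx$states
  e <- matrix(0, ctx$n_s, ctx$n_s, dimnames = list(s, s))
  stay <- c("UCI_faulty_nonuser", "post_explant_HA_compliant",
            "post_explant_HA_noncompliant", "post_explant_no_HA",
            "HA_compliant", "HA_noncompliant", "no_HA", "death")
  for (nm in stay) e[nm, nm] <- 1

  ## exit from the short-term tunnel: long-term sequela or recovery
  e["UCI_st_ae", "UCI_lt_ae"] <- ctx$p_lt
  e["UCI_st_ae", "UCI_well"] <- 1 - ctx$p_lt

  if (ctx$arm != "UCI" || first_cycle) {
    if (first_cycle && ctx$arm == "UCI") {
      ## implantation cycle: adverse-event exposure only, no device events yet
      e["UCI_well", "UCI_st_ae"] <- ctx$p_any
      e["UCI_well", "UCI_lt_ae"] <- (1 - ctx$p_any) * ctx$p_lt
      e["UCI_well", "UCI_well"] <- (1 - ctx$p_any) * (1 - ctx$p_lt)
      e["UCI_lt_ae", "UCI_lt_ae"] <- 1
    } else {
      e["UCI_well", "UCI_well"] <- 1
      e["UCI_lt_ae", "UCI_lt_ae"] <- 1
    }
    return(e)
  }

  ## post-cessation support split after explant
  expl_to <- if (ctx$candidate == "marginal") {
    stats::setNames(c(ctx$p_comp, 1 - ctx$p_comp),
                    c("post_explant_HA_compliant",
                      "post_explant_HA_noncompliant"))
  } else c(post_explant_no_HA = 1)

  for (from in c("UCI_well", "UCI_lt_ae")) {
    home <- from  # re-implant / replacement returns to the source state
    int <- ctx$h_int
    ext <- (1 - int) * ctx$h_ext
    none <- (1 - int) * (1 - ctx$h_ext)
    reimpl <- int * (1 - ctx$p_disc)
    disc <- int * ctx$p_disc
    e[from, home] <- e[from, home] + none + ext * (1 - ctx$p_disc)
    e[from, "UCI_faulty_nonuser"] <- e[from, "UCI_faulty_nonuser"] +
      ext * ctx$p_disc + disc * (1 - ctx$p_expl)
    for (nm in names(expl_to))
      e[from, nm] <- e[from, nm] + disc * ctx$p_expl * expl_to[[nm]]
    if (from == "UCI_well") {
      ## re-implantation re-exposes to surgical adverse events
      e[from, "UCI_st_ae"] <- e[from, "UCI_st_ae"] + reimpl * ctx$p_any
      e[from, "UCI_lt_ae"] <- e[from, "UCI_lt_ae"] +
        reimpl * (1 - ctx$p_any) * ctx$p_lt
      e[from, home] <- e[from, home] +
        reimpl * (1 - ctx$p_any) * (1 - ctx$p_lt)
    } else {
      ## already in the long-term state: stay, adverse events charged as
      ## one-off expected cost/disutility
      e[from, home] <- e[from, home] + reimpl
    }
  }
  e
}

#' Transition matrix for one cycle
#'
#' Assembles the full stochastic matrix over [model_states()] for the given
#' cycle: mortality applies to every living state, the implantation cycle
#' carries the surgical adverse-event exposure, and later cycles carry the
#' device-failure, discontinuation and cessation pathways. Comparator arms
#' only move through mortality.
#'
#' @param cycle 0-based cycle index.
#' @param draw A `uci_parameter_draw`.
#' @param life_table A `uci_life_table`.
#' @param arm `"UCI"`, `"HA"` or `"no_HA"`.
#' @param candidate Candidate type (`"traditional"` or `"marginal"`).
#' @param norm A `uci_norm_curve` for the candidate type.
#' @param schedule A `uci_cost_schedule`; defaults to the schedule built from
#'   the default tables and this draw.
#' @param utable A `uci_utility_table`; defaults to the draw's utilities.
#' @param config A `uci_config`.
#' @return Stochastic matrix with `validate_transition_matrix()` applied.
#' @export
build_transition_matrix <- function(cycle, draw, life_table,
                                    arm = c("UCI", "HA", "no_HA"),
                                    candidate = c("traditional", "marginal"),
                                    norm = NULL, schedule = NULL,
                                    utable = NULL, config = model_config()) {
  arm <- match.arg(arm)
  candidate <- match.arg(candidate)
  if (is.null(utable)) utable <- utility_table_from_draw(draw)
  if (is.null(schedule)) schedule <- build_cost_schedule(default_cost_tables(),
                                                         draw)
  if (is.null(norm))
    norm <- make_norm_curve(config$start_age,
                            utable$baseline[[candidate]] +
                              utable$decrement[[candidate]])
  ctx <- .engine_context(arm, candidate, draw, life_table, norm, schedule,
                         utable, config)
  if (cycle >= ctx$t_cycles)
    stop("cycle ", cycle, " beyond the model horizon (", ctx$t_cycles,
         " cycles)", call. = FALSE)
  .assemble_matrix(ctx, cycle)
}

.assemble_matrix <- function(ctx, cycle) {
  e <- .event_matrix(ctx, first_cycle = (cycle == 0L && ctx$arm == "UCI"))
  qk <- ctx$q[cycle + 1L]
  m <- e * (1 - qk)
  m[, "death"] <- m[, "death"] + qk  # living rows: event mass scaled, + death
  m["death", ] <- 0
  m["death", "death"] <- 1
  validate_transition_matrix(m)
  m
}

#' Validate a transition matrix
#'
#' Checks entries lie in [0, 1] and every row sums to 1 within `tol`; aborts
#' otherwise (an invalid matrix means an invalid model).
#'
#' @param m Square matrix over [model_states()].
#' @param tol Row-sum tolerance.
#' @return `m`, invisibly.
#' @export
validate_transition_matrix <- function(m, tol = 1e-9) {
  if (any(m < -1e-12) || any(m > 1 + 1e-12))
    stop("transition matrix has entries outside [0, 1]", call. = FALSE)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop("transition matrix rows off unity by up to ",
         format(max(abs(rs - 1))), ": model invalid", call. = FALSE)
  invisible(m)
}

## Event flows during interval k+1 given its starting occupancy v (k is the
## 0-based source cycle): `entry` costs are charged undiscounted at time 0,
## `cost` and `disutility` at the interval's discount factor.
.event_flows <- function(ctx, v, k) {
  sch <- ctx$schedule$one_off
  entry <- 0
  cost <- 0
  dis <- 0
  qk <- ctx$q[k + 1L]
  if (ctx$arm == "UCI") {
    if (k == 0L) {
      entry <- entry + sch[["pre_implant_assessment"]] +
        sch[["surgery_plus_device"]]
      cost <- cost + sch[["st_ae_expected"]]
    } else {
      at_risk <- (1 - qk) * (v[["UCI_well"]] + v[["UCI_lt_ae"]])
      m_int <- at_risk * ctx$h_int
      m_reimpl <- m_int * (1 - ctx$p_disc)
      m_expl <- m_int * ctx$p_disc * ctx$p_expl
      m_repl <- at_risk * (1 - ctx$h_int) * ctx$h_ext * (1 - ctx$p_disc)
      cost <- cost +
        m_reimpl * (sch[["re_implant"]] + sch[["st_ae_expected"]]) +
        m_expl * sch[["explant"]] +
        m_repl * sch[["processor_replacement"]]
      ## long-term-state re-implants: expected short-term AE disutility,
      ## charged as a one-off QALY decrement for the six-month episode
      m_reimpl_lt <- (1 - qk) * v[["UCI_lt_ae"]] * ctx$h_int *
        (1 - ctx$p_disc)
      dis <- dis + m_reimpl_lt *
        expected_st_ae_disutility(ctx$utable$st_ae_prob,
                                  ctx$utable$st_disutility) *
        ctx$config$cycle_length
    }
    ## sound processor upgrades: cost-only renewal on the gamma clock,
    ## applied to device users surviving the interval
    device_mass <- (1 - qk) *
      (v[["UCI_well"]] + v[["UCI_st_ae"]] + v[["UCI_lt_ae"]])
    cost <- cost + ctx$ev_up[k + 1L] * device_mass *
      sch[["processor_replacement"]]
    ## marginal candidates keep (and replace) a contralateral hearing aid
    if (ctx$candidate == "marginal") {
      ha_mass <- device_mass + (1 - qk) *
        (v[["UCI_faulty_nonuser"]] + v[["post_explant_HA_compliant"]])
      cost <- cost + ctx$ev_ha[k + 1L] * ha_mass * sch[["hearing_aid_single"]]
    }
  } else if (ctx$arm == "HA") {
    if (k == 0L) entry <- entry + sch[["hearing_aid_pair"]]
    repl_mass <- (1 - qk) * switch(ctx$config$ha_replacement,
      none = 0,
      compliant = v[["HA_compliant"]],
      all = v[["HA_compliant"]] + v[["HA_noncompliant"]])
    cost <- cost + ctx$ev_ha[k + 1L] * repl_mass * sch[["hearing_aid_pair"]]
  }
  list(entry = entry, cost = cost, disutility = dis)
}

.entry_occupancy <- function(ctx) {
  v <- stats::setNames(numeric(ctx$n_s), ctx$states)
  if (ctx$arm == "UCI") {
    v[["UCI_well"]] <- 1
  } else if (ctx$arm == "HA") {
    v[["HA_compliant"]] <- ctx$p_comp
    v[["HA_noncompliant"]] <- 1 - ctx$p_comp
  } else {
    v[["no_HA"]] <- 1
  }
  v
}

#' Run the cohort model for one strategy arm
#'
#' Starts the whole cohort in the arm's entry state(s) at cycle 0, propagates
#' it through per-cycle transition matrices to the terminal age, and
#' accumulates discounted costs and QALYs. One-off event costs are charged in
#' the cycle the transition occurs; recurring costs and utilities accrue on
#' start-of-cycle occupancy (optionally with a half-cycle correction).
#'
#' @inheritParams build_transition_matrix
#' @param arm `"UCI"`, `"HA"` or `"no_HA"`.
#' @param renewals Optional precomputed renewal densities
#'   (internal; lets one draw share them across arms).
#' @return A `uci_strategy_result`: list with `discounted_cost`,
#'   `discounted_qaly`, `trace` (occupancy per cycle), `arm`, `candidate`,
#'   and per-cycle discounted cost/QALY vectors.
#' @export
run_cohort <- function(arm = c("UCI", "HA", "no_HA"),
                       candidate = c("traditional", "marginal"),
                       draw, life_table, norm, schedule, utable,
                       config = model_config(), renewals = NULL) {
  arm <- match.arg(arm)
  candidate <- match.arg(candidate)
  ctx <- .engine_context(arm, candidate, draw, life_table, norm, schedule,
                         utable, config, renewals)
  n_t <- ctx$t_cycles
  trace <- matrix(0, n_t + 1L, ctx$n_s, dimnames = list(NULL, ctx$states))
  v <- .entry_occupancy(ctx)
  trace[1L, ] <- v

  ## event-layer matrices are cycle-invariant apart from the first cycle
  e_first <- .event_matrix(ctx, first_cycle = (arm == "UCI"))
  e_rest <- .event_matrix(ctx, first_cycle = FALSE)
  idx_death <- match("death", ctx$states)

  ## rewards accrue on the occupancy arriving at the end of each interval;
  ## in-cycle event costs share that interval's discount factor, time-0
  ## entry costs are undiscounted
  cost_cycle <- numeric(n_t)
  qaly_cycle <- numeric(n_t)
  entry_cost <- 0
  for (k in 0:(n_t - 1L)) {
    dfk <- ctx$df[k + 1L]
    flows <- .event_flows(ctx, v, k)
    entry_cost <- entry_cost + flows$entry
    e <- if (k == 0L) e_first else e_rest
    w <- as.vector(v %*% e)
    qk <- ctx$q[k + 1L]
    v_next <- w * (1 - qk)
    v_next[idx_death] <- w[idx_death] + qk * (1 - w[idx_death])
    v <- stats::setNames(v_next, ctx$states)
    trace[k + 2L, ] <- v
    qaly_cycle[k + 1L] <- dfk *
      (sum(v * ctx$u_mat[k + 1L, ]) * config$cycle_length - flows$disutility)
    cost_cycle[k + 1L] <- dfk *
      (sum(v * ctx$c_mat[k + 1L, ]) + flows$cost)
  }

  if (config$half_cycle_correction) {
    ## trapezoid accrual: average the occupancy entering and leaving each
    ## interval instead of counting end-of-interval membership only; event
    ## costs stay on their transition cycle
    occ_mid <- (trace[seq_len(n_t), , drop = FALSE] +
                  trace[seq_len(n_t) + 1L, , drop = FALSE]) / 2
    qaly_state <- ctx$df * rowSums(trace[seq_len(n_t) + 1L, , drop = FALSE] *
                                     ctx$u_mat) * config$cycle_length
    qaly_event <- qaly_cycle - qaly_state
    qaly_cycle <- ctx$df * rowSums(occ_mid * ctx$u_mat) *
      config$cycle_length + qaly_event
    cost_state <- ctx$df * rowSums(trace[seq_len(n_t) + 1L, , drop = FALSE] *
                                     ctx$c_mat)
    cost_event <- cost_cycle - cost_state
    cost_cycle <- ctx$df * rowSums(occ_mid * ctx$c_mat) + cost_event
  }

  ## terminal age: any remaining occupancy is forced to death
  trace[n_t + 1L, ] <- c(rep(0, ctx$n_s - 1L), 1)

  structure(list(
    arm = arm, candidate = candidate,
    discounted_cost = entry_cost + sum(cost_cycle),
    discounted_qaly = sum(qaly_cycle),
    entry_cost = entry_cost,
    cost_per_cycle = cost_cycle, qaly_per_cycle = qaly_cycle,
    trace = trace, ages = c(ctx$ages_start, ctx$config$horizon_age),
    config = config), class = "uci_strategy_result")
}

#' @export
print.uci_strategy_result <- function(x, ...) {
  cat(sprintf("Strategy '%s' (%s candidates): cost %.0f GBP, %.3f QALYs\n",
              x$arm, x$candidate, x$discounted_cost, x$discounted_qaly))
  invisible(x)
}

#' Export a cohort trace as a data.frame / CSV
#'
#' @param result A `uci_strategy_result`.
#' @param path Optional CSV path; when given the frame is also written.
#' @return data.frame with cycle, age, one column per state, and the
#'   discounted cost and QALY accrued in each cycle.
#' @export
trace_frame <- function(result, path = NULL) {
  n <- nrow(result$trace)
  df <- data.frame(cycle = 0:(n - 1L), age = result$ages,
                   result$trace, check.names = FALSE)
  ## row 0 carries the undiscounted entry costs; row k the discounted
  ## accrual of interval k
  df$discounted_cost <- c(result$entry_cost, result$cost_per_cycle)
  df$discounted_qaly <- c(0, result$qaly_per_cycle)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Incremental cost-effectiveness comparison of two strategy arms
#'
#' @param intervention,comparator `uci_strategy_result` objects.
#' @return A `uci_ce_comparison`: list with `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` when undefined or dominated) and a `dominance` label
#'   (`"none"`, `"intervention_dominant"`, `"comparator_dominant"`,
#'   `"undefined"`).
#' @export
compute_icer <- function(intervention, comparator) {
  dc <- intervention$discounted_cost - comparator$discounted_cost
  dq <- intervention$discounted_qaly - comparator$discounted_qaly
  dominance <- "none"
  icer <- NA_real_
  if (dq == 0 && dc == 0) {
    dominance <- "undefined"
  } else if (dq == 0) {
    dominance <- if (dc < 0) "intervention_dominant" else "comparator_dominant"
  } else if (dc <= 0 && dq > 0) {
    dominance <- "intervention_dominant"
  } else if (dc >= 0 && dq < 0) {
    dominance <- "comparator_dominant"
  } else {
    icer <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 dominance = dominance,
                 intervention = intervention$arm, comparator = comparator$arm),
            class = "uci_ce_comparison")
}

#' @export
print.uci_ce_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: delta cost %.0f GBP, delta QALY %.3f\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly))
  if (x$dominance == "none") {
    cat(sprintf("ICER: %.0f GBP per QALY\n", x$icer))
  } else cat("ICER not reported:", x$dominance, "\n")
  invisible(x)
}
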