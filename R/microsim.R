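## Individual-level microsimulation of the same decision problem, used to
## cross-validate the cohort engine. It simulates the event layer directly
## (sampled adverse events, device failures, explicit renewal clocks for
## processor upgrades and hearing-aid replacement), so its expectation is an
## independent route to the cohort model's costs and QALYs.

#' Microsimulate individuals through one strategy arm
#'
#' @inheritParams run_cohort
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @return A `uci_microsim_result`: list with mean discounted `cost` and
#'   `qaly`, their Monte Carlo standard errors (`cost_se`, `qaly_se`) and
#'   `n`.
#' @export
simulate_individuals <- function(arm = c("UCI", "HA", "no_HA"),
                                 candidate = c("traditional", "marginal"),
                                 draw, life_table, norm, schedule, utable,
                                 config = model_config(), n = 10000L,
                                 seed = 1L) {
  arm <- match.arg(arm)
  candidate <- match.arg(candidate)
  ctx <- .engine_context(arm, candidate, draw, life_table, norm, schedule,
                         utable, config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  states <- ctx$states
  sid <- stats::setNames(seq_along(states), states)
  sch <- ctx$schedule$one_off
  ae_cost <- ctx$schedule$ae_event_cost
  ae_p <- ctx$utable$st_ae_prob[names(ae_cost)]
  ae_du <- ctx$utable$st_disutility[names(ae_cost)]
  up_shape <- config$upgrade_time_shape
  up_scale <- draw$upgrade_time_months / up_shape / 6      # cycles
  ha_shape <- config$ha_lifetime_shape
  ha_scale <- draw$ha_lifetime_years * 12 / ha_shape / 6   # cycles

  cost <- numeric(n)
  qaly <- numeric(n)
  tunnel_du <- numeric(n)  # personal disutility while in the tunnel state

  ## sample the four adverse events for a set of individuals undergoing
  ## surgery; returns per-individual cost, disutility, and any-event flag
  sample_aes <- function(m) {
    if (m == 0L) return(list(cost = numeric(0), du = numeric(0),
                             any = logical(0)))
    hit <- matrix(stats::runif(m * length(ae_p)), m) <
      matrix(ae_p, m, length(ae_p), byrow = TRUE)
    list(cost = as.vector(hit %*% ae_cost), du = as.vector(hit %*% ae_du),
         any = rowSums(hit) > 0L)
  }

  state <- rep(switch(arm, UCI = sid[["UCI_well"]], HA = NA_integer_,
                      no_HA = sid[["no_HA"]]), n)
  if (arm == "HA") {
    compliant <- stats::runif(n) < ctx$p_comp
    state <- ifelse(compliant, sid[["HA_compliant"]],
                    sid[["HA_noncompliant"]])
    cost <- cost + sch[["hearing_aid_pair"]]
  }
  up_clock <- stats::rgamma(n, up_shape, scale = up_scale)
  ha_clock <- stats::rgamma(n, ha_shape, scale = ha_scale)

  idx_death <- sid[["death"]]
  device_states <- sid[c("UCI_well", "UCI_st_ae", "UCI_lt_ae")]
  ha_wearer_states <- if (arm == "UCI" && candidate == "marginal") {
    sid[c("UCI_well", "UCI_st_ae", "UCI_lt_ae", "UCI_faulty_nonuser",
          "post_explant_HA_compliant")]
  } else if (arm == "HA") {
    switch(config$ha_replacement,
           none = integer(0),
           compliant = sid[["HA_compliant"]],
           all = sid[c("HA_compliant", "HA_noncompliant")])
  } else integer(0)

  expl_targets <- function(m) {
    if (candidate == "marginal") {
      ifelse(stats::runif(m) < ctx$p_comp, sid[["post_explant_HA_compliant"]],
             sid[["post_explant_HA_noncompliant"]])
    } else rep(sid[["post_explant_no_HA"]], m)
  }

  for (k in 0:(ctx$t_cycles - 1L)) {
    dfk <- ctx$df[k + 1L]  # discounts interval k+1 (events and its accrual)
    alive <- state != idx_death
    if (!any(alive)) break

    ## mortality
    dies <- alive & (stats::runif(n) < ctx$q[k + 1L])
    surv <- alive & !dies

    new_state <- state
    new_state[dies] <- idx_death

    if (arm == "UCI" && k == 0L) {
      ## implantation: assessment and surgery costed for the whole cohort,
      ## adverse events sampled per individual at surgery
      cost <- cost + sch[["pre_implant_assessment"]] +
        sch[["surgery_plus_device"]]
      ae <- sample_aes(n)
      cost <- cost + dfk * ae$cost
      who <- which(surv)
      lt_hit <- stats::runif(n) < ctx$p_lt
      new_state[who] <- ifelse(ae$any[who], sid[["UCI_st_ae"]],
                               ifelse(lt_hit[who], sid[["UCI_lt_ae"]],
                                      sid[["UCI_well"]]))
      hit_t <- who[ae$any[who]]
      tunnel_du[hit_t] <- ae$du[hit_t]
    } else if (arm == "UCI") {
      ## tunnel exits
      who <- which(surv & state == sid[["UCI_st_ae"]])
      if (length(who)) {
        lt_hit <- stats::runif(length(who)) < ctx$p_lt
        new_state[who] <- ifelse(lt_hit, sid[["UCI_lt_ae"]],
                                 sid[["UCI_well"]])
      }
      ## device failure pathway from the device-bearing chronic states
      who <- which(surv & (state == sid[["UCI_well"]] |
                             state == sid[["UCI_lt_ae"]]))
      if (length(who)) {
        m <- length(who)
        u1 <- stats::runif(m)
        int_fail <- u1 < ctx$h_int
        ext_fail <- !int_fail & (stats::runif(m) < ctx$h_ext)
        disc <- stats::runif(m) < ctx$p_disc
        ## internal failure, re-implant
        ri <- which(int_fail & !disc)
        if (length(ri)) {
          tgt <- who[ri]
          cost[tgt] <- cost[tgt] + dfk * sch[["re_implant"]]
          ae <- sample_aes(length(tgt))
          cost[tgt] <- cost[tgt] + dfk * ae$cost
          from_well <- state[tgt] == sid[["UCI_well"]]
          lt_hit <- stats::runif(length(tgt)) < ctx$p_lt
          new_state[tgt[from_well]] <-
            ifelse(ae$any[from_well], sid[["UCI_st_ae"]],
                   ifelse(lt_hit[from_well], sid[["UCI_lt_ae"]],
                          sid[["UCI_well"]]))
          tunnel_du[tgt[from_well & ae$any]] <- ae$du[from_well & ae$any]
          ## already long-term: stay, take the episode as one-off disutility
          qaly[tgt[!from_well]] <- qaly[tgt[!from_well]] -
            dfk * ae$du[!from_well] * config$cycle_length
        }
        ## internal failure, discontinue: explant or keep the faulty device
        dc <- which(int_fail & disc)
        if (length(dc)) {
          tgt <- who[dc]
          expl <- stats::runif(length(tgt)) < ctx$p_expl
          cost[tgt[expl]] <- cost[tgt[expl]] + dfk * sch[["explant"]]
          new_state[tgt[expl]] <- expl_targets(sum(expl))
          new_state[tgt[!expl]] <- sid[["UCI_faulty_nonuser"]]
        }
        ## external failure: replace or cease
        ex <- which(ext_fail)
        if (length(ex)) {
          tgt <- who[ex]
          repl <- !disc[ex]
          cost[tgt[repl]] <- cost[tgt[repl]] +
            dfk * sch[["processor_replacement"]]
          new_state[tgt[!repl]] <- sid[["UCI_faulty_nonuser"]]
        }
      }
    }

    ## renewal clocks (processor upgrades; hearing-aid replacement)
    if (arm == "UCI") {
      on_dev <- surv & state %in% device_states
      up_clock[on_dev] <- up_clock[on_dev] - 1
      due <- which(on_dev & up_clock <= 0)
      while (length(due)) {
        cost[due] <- cost[due] + dfk * sch[["processor_replacement"]]
        up_clock[due] <- up_clock[due] +
          stats::rgamma(length(due), up_shape, scale = up_scale)
        due <- due[up_clock[due] <= 0]
      }
    }
    if (length(ha_wearer_states)) {
      wears <- surv & state %in% ha_wearer_states
      ha_clock[wears] <- ha_clock[wears] - 1
      due <- which(wears & ha_clock <= 0)
      unit <- if (arm == "HA") sch[["hearing_aid_pair"]] else
        sch[["hearing_aid_single"]]
      while (length(due)) {
        cost[due] <- cost[due] + dfk * unit
        ha_clock[due] <- ha_clock[due] +
          stats::rgamma(length(due), ha_shape, scale = ha_scale)
        due <- due[ha_clock[due] <= 0]
      }
    }
    state <- new_state

    ## rewards accrue on the state arrived at (end of interval k+1)
    u_now <- ctx$u_mat[k + 1L, state]
    in_tunnel <- state == sid[["UCI_st_ae"]]
    if (any(in_tunnel))  # personal adverse-event mix, not the tunnel average
      u_now[in_tunnel] <- pmax(ctx$u_mat[k + 1L, sid[["UCI_well"]]] -
                                 tunnel_du[in_tunnel], 0)
    qaly <- qaly + dfk * u_now * config$cycle_length
    cost <- cost + dfk * ctx$c_mat[k + 1L, state]
  }

  structure(list(cost = mean(cost), qaly = mean(qaly),
                 cost_se = stats::sd(cost) / sqrt(n),
                 qaly_se = stats::sd(qaly) / sqrt(n), n = n,
                 arm = arm, candidate = candidate),
            class = "uci_microsim_result")
}

#' @export
print.uci_microsim_result <- function(x, ...) {
  cat(sprintf(
    "Microsimulation '%s' (%s, n = %d): cost %.0f (SE %.0f) GBP, %.3f (SE %.4f) QALYs\n",
    x$arm, x$candidate, x$n, x$cost, x$cost_se, x$qaly, x$qaly_se))
  invisible(x)
}
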