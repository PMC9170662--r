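#' Expected short-term adverse-event disutility per implantation
#'
#' Weighted average of the event disutilities using the event probabilities
#' as weights; it applies for exactly one six-month cycle after surgery.
#'
#' @param probs Named event probabilities.
#' @param disutils Named event disutilities (same names).
#' @return Expected utility decrement.
#' @examples
#' expected_st_ae_disutility(c(vertigo = 0.194), c(vertigo = 0.033))
#' @export
expected_st_ae_disutility <- function(probs, disutils) {
  stopifnot(all(probs >= 0 & probs <= 1))
  disutils <- disutils[names(probs)]
  if (anyNA(disutils))
    stop("missing disutilities for: ",
         paste(names(probs)[is.na(disutils)], collapse = ", "), call. = FALSE)
  sum(probs * disutils)
}

#' Probability of experiencing at least one short-term adverse event
#'
#' Events are treated as independent, so the short-term tunnel state is
#' entered with probability `1 - prod(1 - p_i)`.
#'
#' @param table A `uci_utility_table`.
#' @return Probability in [0, 1].
#' @export
p_st_ae_any <- function(table) 1 - prod(1 - table$st_ae_prob)

#' Disutility of the short-term adverse-event tunnel state
#'
#' Conditional expected disutility given at least one event, so that the
#' cohort-level decrement (tunnel occupancy times tunnel disutility) equals
#' the probability-weighted average disutility exactly.
#'
#' @param table A `uci_utility_table`.
#' @return Utility decrement applied in the tunnel state.
#' @export
st_tunnel_disutility <- function(table) {
  p_any <- p_st_ae_any(table)
  if (p_any == 0) return(0)
  expected_st_ae_disutility(table$st_ae_prob, table$st_disutility) / p_any
}

#' Health-state utility at a given age
#'
#' Utilities enter at their start-age values and then age with the general
#' population: the norm-curve difference from the start age is added
#' (`u(age) = u(start) + norm(age) - norm(start)`), floored at 0 and capped
#' at the norm. Death is 0. Implant states add the candidate-specific
#' increment; adverse-event states subtract the applicable disutility;
#' states without hearing support (and non-compliant hearing-aid users) take
#' the unaided traditional baseline.
#'
#' @param state One of [model_states()].
#' @param age Current age in years (`>= start_age`).
#' @param candidate `"traditional"` (no prior hearing-aid benefit) or
#'   `"marginal"` (some prior benefit).
#' @param norm A `uci_norm_curve` for this candidate type.
#' @param table A `uci_utility_table`.
#' @param start_age Cohort entry age (years).
#' @return Utility in [0, 1].
#' @export
state_utility <- function(state, age, candidate = c("traditional", "marginal"),
                          norm, table, start_age = 52.8) {
  candidate <- match.arg(candidate)
  if (any(age < start_age))
    stop("age precedes the cohort start age", call. = FALSE)
  base <- table$baseline[[candidate]]
  gain <- table$uci_increment[[candidate]]
  unaided <- table$baseline[["traditional"]]
  u0 <- switch(state,
    UCI_well                     = base + gain,
    UCI_st_ae                    = base + gain - st_tunnel_disutility(table),
    UCI_lt_ae                    = base + gain - table$lt_disutility[["vertigo"]],
    UCI_faulty_nonuser           = base,
    post_explant_HA_compliant    = base,
    post_explant_HA_noncompliant = unaided,
    post_explant_no_HA           = unaided,
    HA_compliant                 = base,
    HA_noncompliant              = unaided,
    no_HA                        = unaided,
    death                        = return(rep(0, length(age))),
    stop("unknown health state '", state, "'", call. = FALSE)
  )
  u <- u0 + norm(age) - norm(start_age)
  pmin(pmax(u, 0), norm(age))
}

#' QALYs accrued over one cycle at a given utility
#'
#' @param utility Utility weight in [0, 1].
#' @param cycle_length Cycle length in years (0.5 in this model family).
#' @return QALYs for the cycle.
#' @export
qaly_weight <- function(utility, cycle_length = 0.5) utility * cycle_length
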