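#' Total cost of a resource block
#'
#' Each item costs `n_visits * units_per_visit * unit_cost`; missing
#' `n_visits` counts as 1.
#'
#' @param items data.frame with columns `n_visits`, `units_per_visit`,
#'   `unit_cost` (a block of [default_cost_tables()]).
#' @return Total cost in GBP.
#' @export
sum_resource_block <- function(items) {
  if (NROW(items) == 0L) return(0)
  nv <- items$n_visits
  nv[is.na(nv)] <- 1
  if (any(nv < 0 | items$units_per_visit < 0 | items$unit_cost < 0,
          na.rm = TRUE))
    stop("negative entries in resource block", call. = FALSE)
  sum(nv * items$units_per_visit * items$unit_cost)
}

.block_total <- function(tables, block) {
  rows <- tables[tables$block == block, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("cost tables are missing block '", block, "'", call. = FALSE)
  sum_resource_block(rows)
}

.ae_item_cost <- function(tables, labels) {
  rows <- tables[tables$block == "ae_short_term" & tables$label %in% labels, ,
                 drop = FALSE]
  if (nrow(rows) == 0L)
    stop("cost tables are missing short-term adverse-event items: ",
         paste(labels, collapse = ", "), call. = FALSE)
  sum_resource_block(rows)
}

#' Expected short-term adverse-event cost per implantation
#'
#' The probability-weighted sum of per-event management costs, charged once
#' in the surgery cycle.
#'
#' @param ae_probs Named probabilities (events as in the utility table).
#' @param ae_costs Named per-event costs, same names.
#' @return Expected cost in GBP.
#' @examples
#' expected_st_ae_cost(c(a = 0.1, b = 0.2), c(a = 31, b = 41))
#' @export
expected_st_ae_cost <- function(ae_probs, ae_costs) {
  stopifnot(all(ae_probs >= 0 & ae_probs <= 1))
  ae_costs <- ae_costs[names(ae_probs)]
  if (anyNA(ae_costs))
    stop("missing adverse-event costs for: ",
         paste(names(ae_probs)[is.na(ae_costs)], collapse = ", "),
         call. = FALSE)
  sum(ae_probs * ae_costs)
}

#' Build the cost schedule for one parameter draw
#'
#' Converts the resource-use tables into the event and per-cycle costs the
#' cohort engine charges, scaled by the draw's per-block cost multipliers:
#'
#' * one-off event costs: pre-implant assessment (loaded by the eligibility
#'   proportion, since every assessed candidate is costed but only the
#'   eligible fraction is implanted), surgery + device, sound-processor
#'   replacement/upgrade, explant, re-implant, hearing aids (single / pair),
#'   and the expected short-term adverse-event cost;
#' * recurring per-cycle costs: year-1 programming/rehabilitation (first two
#'   cycles), year-2+ tuning/maintenance/administration (from cycle 2), and
#'   the long-term vertigo follow-up (one GP visit per year for life).
#'
#' @param tables A `uci_cost_tables` data.frame ([default_cost_tables()]).
#' @param draw A `uci_parameter_draw`.
#' @return A `uci_cost_schedule`: list with components `one_off`, `recurring`
#'   and `ae_event_cost` (per-event short-term AE costs, for the
#'   microsimulation).
#' @export
build_cost_schedule <- function(tables, draw) {
  stopifnot(inherits(tables, "uci_cost_tables"))
  needed <- c("assessment", "surgery", "hearing_aid", "year1", "maintenance",
              "processor", "explant", "reimplant", "ae_short_term",
              "ae_long_term")
  missing <- setdiff(needed, unique(tables$block))
  if (length(missing))
    stop("cost tables are missing block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  ha_rows <- tables[tables$block == "hearing_aid", ]
  single <- sum_resource_block(ha_rows[ha_rows$label == "one_hearing_aid", ])
  pair <- sum_resource_block(ha_rows[ha_rows$label == "pair_of_hearing_aids", ])

  ae_event <- c(
    dysgeusia       = .ae_item_cost(tables, "dysgeusia_gp_visit"),
    vertigo         = .ae_item_cost(tables, "vertigo_gp_visit"),
    tinnitus        = .ae_item_cost(tables, "tinnitus_gp_visit"),
    wound_infection = .ae_item_cost(tables, c("infection_gp_visit",
                                              "infection_antibiotics"))
  ) * draw$c_adverse_event

  st_probs <- c(dysgeusia = draw$p_dysgeusia, vertigo = draw$p_st_vertigo,
                tinnitus = draw$p_tinnitus, wound_infection = draw$p_infection)

  one_off <- c(
    pre_implant_assessment =
      .block_total(tables, "assessment") * draw$c_assessment /
        draw$prop_eligible,
    surgery_plus_device =
      .block_total(tables, "surgery") * draw$c_surgery_device,
    processor_replacement =
      .block_total(tables, "processor") * draw$c_processor,
    explant = .block_total(tables, "explant") * draw$c_explant,
    re_implant = .block_total(tables, "reimplant") * draw$c_reimplant,
    hearing_aid_single = single * draw$c_hearing_aid,
    hearing_aid_pair = pair * draw$c_hearing_aid,
    st_ae_expected = expected_st_ae_cost(st_probs, ae_event)
  )
  recurring <- c(
    uci_year1_per_cycle =
      .block_total(tables, "year1") * draw$c_year1 / 2,
    uci_maintenance_per_cycle =
      .block_total(tables, "maintenance") * draw$c_maintenance / 2,
    lt_ae_per_cycle =
      .block_total(tables, "ae_long_term") * draw$c_adverse_event / 2
  )
  structure(list(one_off = one_off, recurring = recurring,
                 ae_event_cost = ae_event),
            class = "uci_cost_schedule")
}

#' @export
print.uci_cost_schedule <- function(x, ...) {
  cat("Cost schedule (GBP)\n one-off events:\n")
  print(round(x$one_off, 2))
  cat(" recurring per 6-month cycle:\n")
  print(round(x$recurring, 2))
  invisible(x)
}

#' Export a cost schedule to JSON for audit
#'
#' @param schedule A `uci_cost_schedule`.
#' @param path File path.
#' @export
write_cost_schedule <- function(schedule, path) {
  jsonlite::write_json(lapply(unclass(schedule), as.list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
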