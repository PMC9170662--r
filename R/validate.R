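#' Internal validation battery
#'
#' Runs the model's full self-check battery: prior round-trip (fitted
#' distributions reproduce their printed means), draw admissibility
#' (probabilities in [0, 1], times and costs positive), transition-matrix
#' row sums, cohort conservation and death monotonicity, a null-effect run
#' (no implant benefit and no events implies zero incremental QALYs), an
#' extreme-mortality run (everyone dies in the first cycle, so lifetime cost
#' collapses to the entry costs), and a microsimulation cross-check of the
#' cohort engine.
#'
#' @param model A `uci_model`.
#' @param n_draws Random draws used for the admissibility and row-sum checks.
#' @param n_microsim Individuals in the microsimulation cross-check.
#' @param seed Integer seed.
#' @return A `uci_validation` data.frame (check, pass, detail) with
#'   attribute `all_passed`.
#' @export
validate_model <- function(model, n_draws = 200L, n_microsim = 4000L,
                           seed = 1L) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  ps <- model$params

  ## 1. fitted priors reproduce their means
  err <- vapply(seq_len(nrow(ps)), function(i) {
    switch(ps$family[i],
           beta = abs(ps$par1[i] / (ps$par1[i] + ps$par2[i]) - ps$mean[i]),
           gamma = abs(ps$par1[i] * ps$par2[i] - ps$mean[i]),
           fixed = 0)
  }, numeric(1L))
  add("prior_mean_round_trip", max(err) < 1e-6,
      sprintf("max |fitted mean - printed mean| = %.2e", max(err)))

  ## 2. draw admissibility
  ok <- TRUE
  worst <- ""
  for (k in seq_len(n_draws)) {
    d <- sample_draw(ps, k, seed)
    for (nm in names(d)) {
      fam <- ps[nm, "family"]
      v <- d[[nm]]
      bad <- (fam == "beta" && (v < 0 || v > 1)) || (fam == "gamma" && v <= 0)
      if (bad) {
        ok <- FALSE
        worst <- paste0(nm, " = ", v, " (draw ", k, ")")
      }
    }
  }
  add("draw_admissibility", ok,
      if (ok) sprintf("%d draws in bounds", n_draws) else worst)

  ## 3. transition-matrix row sums (all arms, candidates, sampled cycles
  ## and draws; build_transition_matrix aborts on violation)
  rowsum_err <- 0
  ok <- tryCatch({
    for (d_id in c(0L, seq_len(5L))) {
      d <- sample_draw(ps, d_id, seed)
      ut <- utility_table_from_draw(d)
      sch <- build_cost_schedule(model$cost_tables, d)
      for (arm in c("UCI", "HA", "no_HA")) {
        cand <- if (arm == "HA") "marginal" else "traditional"
        for (cy in c(0L, 1L, 10L, 50L, 90L)) {
          m <- build_transition_matrix(cy, d, model$life_table, arm, cand,
                                       model$norms[[cand]], sch, ut,
                                       model$config)
          rowsum_err <- max(rowsum_err, abs(rowSums(m) - 1))
        }
      }
    }
    TRUE
  }, error = function(e) FALSE)
  add("transition_row_sums", ok && rowsum_err < 1e-12,
      sprintf("max |row sum - 1| = %.2e", rowsum_err))

  ## 4. cohort conservation and monotone death
  d0 <- mean_draw(ps)
  ut0 <- utility_table_from_draw(d0)
  sch0 <- build_cost_schedule(model$cost_tables, d0)
  cons_ok <- TRUE
  detail <- ""
  for (arm in c("UCI", "HA", "no_HA")) {
    cand <- if (arm == "HA") "marginal" else "traditional"
    r <- run_cohort(arm, cand, d0, model$life_table, model$norms[[cand]],
                    sch0, ut0, model$config)
    cerr <- max(abs(rowSums(r$trace) - 1))
    dmono <- all(diff(r$trace[, "death"]) >= -1e-12)
    if (cerr > 1e-10 || !dmono) {
      cons_ok <- FALSE
      detail <- sprintf("%s: conservation %.2e, death monotone %s", arm,
                        cerr, dmono)
    }
  }
  add("cohort_conservation", cons_ok,
      if (cons_ok) "occupancy sums to 1, death monotone" else detail)

  ## 5. null effect: no benefit, no events -> zero incremental QALYs
  dn <- mean_draw(ps)
  dn$u_gain_traditional <- 0
  dn$p_internal_failure <- 0
  dn$p_external_failure <- 0
  for (nm in c("p_dysgeusia", "p_st_vertigo", "p_infection", "p_tinnitus",
               "p_lt_vertigo")) dn[[nm]] <- 0
  utn <- utility_table_from_draw(dn)
  schn <- build_cost_schedule(model$cost_tables, dn)
  un <- run_cohort("UCI", "traditional", dn, model$life_table,
                   model$norms$traditional, schn, utn, model$config)
  cn <- run_cohort("no_HA", "traditional", dn, model$life_table,
                   model$norms$traditional, schn, utn, model$config)
  dq <- un$discounted_qaly - cn$discounted_qaly
  add("null_effect", abs(dq) < 1e-9,
      sprintf("incremental QALYs with null effect = %.2e", dq))

  ## 6. extreme mortality: first-cycle death leaves only the entry costs
  lt1 <- model$life_table
  lt1$q_annual[] <- 1
  ue <- run_cohort("UCI", "traditional", d0, lt1, model$norms$traditional,
                   sch0, ut0, model$config)
  expected <- sum(sch0$one_off[c("pre_implant_assessment",
                                 "surgery_plus_device")]) +
    sch0$one_off[["st_ae_expected"]] *
      discount_factor(1, model$config$discount_rate)
  rel <- abs(ue$discounted_cost - expected) / expected
  add("extreme_mortality_cost", rel < 0.01,
      sprintf("cost %.2f vs entry costs %.2f (rel %.4f)", ue$discounted_cost,
              expected, rel))

  ## 7. microsimulation cross-check (3 Monte Carlo SEs)
  ms <- simulate_individuals("UCI", "traditional", d0, model$life_table,
                             model$norms$traditional, sch0, ut0,
                             model$config, n = n_microsim, seed = seed)
  co <- run_cohort("UCI", "traditional", d0, model$life_table,
                   model$norms$traditional, sch0, ut0, model$config)
  zc <- abs(co$discounted_cost - ms$cost) / ms$cost_se
  zq <- abs(co$discounted_qaly - ms$qaly) / ms$qaly_se
  add("microsim_cross_check", zc < 3 && zq < 3,
      sprintf("cost z = %.2f, QALY z = %.2f (n = %d)", zc, zq, n_microsim))

  out <- do.call(rbind, checks)
  attr(out, "all_passed") <- all(out$pass)
  class(out) <- c("uci_validation", "data.frame")
  out
}

#' @export
print.uci_validation <- function(x, ...) {
  cat("Internal validation battery:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-24s %s\n", if (x$pass[i]) "PASS" else "FAIL",
                x$check[i], x$detail[i]))
  cat(if (attr(x, "all_passed")) "All checks passed.\n" else
    "SOME CHECKS FAILED.\n")
  invisible(x)
}
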