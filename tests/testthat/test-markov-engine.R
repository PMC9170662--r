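test_that("discount factors follow (1 + r)^(-cycle/2)", {
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_equal(discount_factor(2, 0.035), 1 / 1.035)
  expect_equal(discount_factor(1, 0.035), 1.035^(-0.5), tolerance = 1e-9)
  expect_equal(discount_factor(0, 0.035), 1)
})

test_that("per-cycle mortality halves the annual probability correctly", {
  expect_equal(per_cycle_mortality(flat_life_table(0), 50), 0)
  expect_equal(per_cycle_mortality(flat_life_table(1), 50), 1)
  expect_equal(per_cycle_mortality(flat_life_table(0.04), 50),
               1 - 0.96^0.5, tolerance = 1e-12)
  ## ages beyond the table are fatal
  expect_equal(per_cycle_mortality(flat_life_table(0.04), 200), 1)
})

test_that("time-dependent event probabilities come from conditional survival", {
  lam <- 0.03
  s_exp <- function(t) exp(-lam * t)
  p <- time_dependent_event_prob(s_exp, c(0, 10, 100), 6)
  expect_equal(p, rep(1 - exp(-lam * 6), 3), tolerance = 1e-12)  # memoryless
  expect_equal(time_dependent_event_prob(function(t) rep(1, length(t)),
                                         5, 6), 0)
  ## telescoping product over 40 years recovers the cumulative gamma mass
  fit <- fit_gamma_from_mean_ci(106, 29, 232)
  s_g <- function(t) stats::pgamma(t, shape = fit[1], scale = fit[2],
                                   lower.tail = FALSE)
  t_grid <- seq(0, 474, by = 6)
  p_k <- time_dependent_event_prob(s_g, t_grid, 6)
  expect_equal(1 - prod(1 - p_k), 1 - s_g(480), tolerance = 1e-6)
  ## exhausted clock
  expect_equal(time_dependent_event_prob(function(t) ifelse(t < 1, 1, 0),
                                         5, 6), 0)
})

test_that("no events and no mortality leave the cohort where it is", {
  d <- test_mean_draw()
  d$p_internal_failure <- 0
  d$p_external_failure <- 0
  for (nm in c("p_dysgeusia", "p_st_vertigo", "p_infection", "p_tinnitus",
               "p_lt_vertigo")) d[[nm]] <- 0
  m <- build_transition_matrix(5, d, flat_life_table(0), "UCI",
                               "traditional", config = test_model()$config)
  keep <- setdiff(model_states(), "UCI_st_ae")
  expect_equal(m[keep, keep], diag(length(keep)),
               ignore_attr = TRUE)
  ## the tunnel state still empties after its single cycle
  expect_equal(unname(m["UCI_st_ae", "UCI_well"]), 1)
})

test_that("certain mortality sends every living state to death", {
  m <- build_transition_matrix(3, test_mean_draw(), flat_life_table(1),
                               "UCI", "traditional",
                               config = test_model()$config)
  expect_equal(unname(m[, "death"]), rep(1, nrow(m)))
})

test_that("surgery exposes survivors to the joint adverse-event probability", {
  mod <- test_model()
  d <- test_mean_draw()
  ut <- test_utable()
  m0 <- build_transition_matrix(0, d, mod$life_table, "UCI", "traditional",
                                mod$norms$traditional, test_schedule(), ut,
                                mod$config)
  v0 <- as.numeric(model_states() == "UCI_well")
  v1 <- as.vector(v0 %*% m0)
  names(v1) <- model_states()
  q0 <- per_cycle_mortality(mod$life_table, 52.8)
  expect_equal(unname(v1["UCI_st_ae"]), (1 - q0) * p_st_ae_any(ut),
               tolerance = 1e-12)
  expect_equal(unname(v1["UCI_lt_ae"]),
               (1 - q0) * (1 - p_st_ae_any(ut)) * 0.014, tolerance = 1e-12)
  expect_equal(unname(v1["death"]), q0, tolerance = 1e-12)
})

test_that("transition rows are stochastic across cycles, arms and draws", {
  mod <- test_model()
  worst <- 0
  for (draw_id in 0:3) {
    d <- sample_draw(mod$params, draw_id, seed = 2L)
    for (arm in c("UCI", "HA", "no_HA")) {
      cand <- if (arm == "HA") "marginal" else "traditional"
      for (cy in c(0, 1, 20, 80)) {
        m <- build_transition_matrix(cy, d, mod$life_table, arm, cand,
                                     mod$norms[[cand]], config = mod$config)
        worst <- max(worst, abs(rowSums(m) - 1))
        expect_true(all(m >= 0 & m <= 1))
      }
    }
  }
  expect_lt(worst, 1e-12)
  expect_error(validate_transition_matrix(diag(2) * 1.5), "outside")
  bad <- diag(11) * 0.99
  expect_error(validate_transition_matrix(bad), "model invalid")
})

test_that("a two-state cohort reproduces the geometric QALY closed form", {
  q_cycle <- 0.3
  lt <- flat_life_table(1 - (1 - q_cycle)^2)  # annual q giving q_cycle
  ut <- default_utility_table()
  ut$baseline[["traditional"]] <- 1
  ut$uci_increment[["traditional"]] <- 0
  cfg <- model_config(discount_rate = 0)
  r <- run_cohort("no_HA", "traditional", test_mean_draw(), lt,
                  make_norm_curve(52.8, 1, 0), test_schedule(), ut, cfg)
  expect_equal(r$discounted_qaly, 0.5 * (1 - q_cycle) / q_cycle,
               tolerance = 1e-9)
  expect_equal(r$discounted_cost, 0)
})

test_that("with no discounting or mortality a 10-year horizon yields 10 QALYs", {
  lt <- flat_life_table(0)
  ut <- default_utility_table()
  ut$baseline[["traditional"]] <- 1
  ut$uci_increment[["traditional"]] <- 0
  cfg <- model_config(horizon_age = 62.8, discount_rate = 0)
  r <- run_cohort("no_HA", "traditional", test_mean_draw(), lt,
                  make_norm_curve(52.8, 1, 0), test_schedule(), ut, cfg)
  expect_equal(r$discounted_qaly, 10, tolerance = 1e-12)
})

test_that("cohort occupancy is conserved and death is monotone", {
  mod <- test_model()
  for (arm in c("UCI", "HA")) {
    cand <- if (arm == "HA") "marginal" else "traditional"
    r <- run_cohort(arm, cand, test_mean_draw(), mod$life_table,
                    mod$norms[[cand]], test_schedule(), test_utable(),
                    mod$config)
    expect_lt(max(abs(rowSums(r$trace) - 1)), 1e-10)
    expect_true(all(diff(r$trace[, "death"]) >= -1e-12))
    expect_lte(r$discounted_qaly, mod$config$horizon_age -
                 mod$config$start_age)
    ## trace export matches the accumulated totals
    tf <- trace_frame(r)
    expect_equal(sum(tf$discounted_cost), r$discounted_cost)
    expect_equal(sum(tf$discounted_qaly), r$discounted_qaly)
  }
})

test_that("QALYs fall strictly as the discount rate rises", {
  mod <- test_model()
  qalys <- vapply(c(0.015, 0.035, 0.05), function(r) {
    cfg <- mod$config
    cfg$discount_rate <- r
    base_case(mod, "vs_noHA", config = cfg)$uci$discounted_qaly
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))
})

test_that("ICERs and dominance are computed from the strategy results", {
  sr <- function(cost, qaly) structure(list(discounted_cost = cost,
                                            discounted_qaly = qaly,
                                            arm = "x"),
                                       class = "uci_strategy_result")
  cmp <- compute_icer(sr(37985, 10), sr(0, 10 - 3.18))
  expect_equal(cmp$icer, 37985 / 3.18, tolerance = 1e-12)  # ~11,945
  expect_equal(round(cmp$icer), 11945)
  dom <- compute_icer(sr(-100, 5), sr(0, 4))
  expect_equal(dom$dominance, "intervention_dominant")
  expect_true(is.na(dom$icer))
  und <- compute_icer(sr(10, 5), sr(10, 5))
  expect_equal(und$dominance, "undefined")
  expect_true(is.na(und$icer))
  worse <- compute_icer(sr(10, 4), sr(0, 5))
  expect_equal(worse$dominance, "comparator_dominant")
})

test_that("half-cycle correction shifts accruals by less than one cycle", {
  mod <- test_model()
  cfg <- mod$config
  cfg$half_cycle_correction <- TRUE
  bc0 <- base_case(mod, "vs_noHA")
  bc1 <- base_case(mod, "vs_noHA", config = cfg)
  ## correction adds at most half of one cycle's full-health accrual
  expect_gt(bc1$uci$discounted_qaly, bc0$uci$discounted_qaly)
  expect_lt(bc1$uci$discounted_qaly - bc0$uci$discounted_qaly, 0.25)
})
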