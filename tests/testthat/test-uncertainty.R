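test_that("PSA is reproducible and lives in the northeast quadrant", {
  mod <- test_model()
  p1 <- run_psa(mod, n = 120, seed = 42, scenario = "vs_HA")
  p2 <- run_psa(mod, n = 120, seed = 42, scenario = "vs_HA")
  expect_identical(p1$draws, p2$draws)
  expect_equal(p1$n_resampled, 0)
  ## implant arm always costs more and yields more QALYs on this fixture
  expect_true(all(p1$draws$dcost > 0))
  expect_true(all(p1$draws$dqaly > 0))
  ## different seeds move the draws
  p3 <- run_psa(mod, n = 120, seed = 43, scenario = "vs_HA")
  expect_false(identical(p1$draws$dcost, p3$draws$dcost))
})

test_that("PSA mean incremental QALYs track the deterministic base case", {
  mod <- test_model()
  psa <- run_psa(mod, n = 400, seed = 9, scenario = "vs_noHA")
  bc <- base_case(mod, "vs_noHA")
  se <- stats::sd(psa$draws$dqaly) / sqrt(psa$n)
  expect_lt(abs(psa$mean_dqaly - bc$icer$delta_qaly), 3 * se)
  ## percentile intervals bracket the deterministic value
  expect_gt(bc$icer$delta_qaly, psa$ci_dqaly[1])
  expect_lt(bc$icer$delta_qaly, psa$ci_dqaly[2])
  expect_gt(bc$icer$delta_cost, psa$ci_dcost[1])
  expect_lt(bc$icer$delta_cost, psa$ci_dcost[2])
})

test_that("a PSA with all distributions collapsed equals the base case", {
  mod <- test_model()
  fixed <- mod$params
  fixed$family[] <- "fixed"
  mod_fixed <- uci_model(params = fixed, life_table = mod$life_table,
                         norm_decline = mod$norm_decline,
                         config = mod$config)
  psa <- run_psa(mod_fixed, n = 3, seed = 1, scenario = "vs_noHA")
  bc <- base_case(mod, "vs_noHA")
  expect_equal(psa$draws$dcost, rep(bc$icer$delta_cost, 3))
  expect_equal(psa$draws$dqaly, rep(bc$icer$delta_qaly, 3))
})

test_that("the CEAC follows the net-monetary-benefit rule", {
  dominant <- data.frame(dcost = c(-5, -10), dqaly = c(1, 2))
  expect_equal(ceac(dominant, c(0, 10000, 30000))$probability, c(1, 1, 1))
  costly <- data.frame(dcost = c(5, 10), dqaly = c(1, 2))
  expect_equal(ceac(costly, 0)$probability, 0)
  ## monotone non-decreasing in the threshold when all gains are positive
  mod <- test_model()
  psa <- run_psa(mod, n = 120, seed = 42, scenario = "vs_HA")
  expect_true(all(diff(psa$ceac$probability) >= 0))
  expect_true(all(psa$ceac$probability >= 0 & psa$ceac$probability <= 1))
  ## hand-check one threshold against the draws
  expect_equal(prob_cost_effective(psa, 20000),
               mean(20000 * psa$draws$dqaly - psa$draws$dcost >= 0))
})

test_that("CEAC at the 2.5th-percentile ICER is near 0.975 here", {
  ## all draws fall in the northeast quadrant, so NMB >= 0 at threshold
  ## lambda is equivalent to ICER <= lambda and the CEAC is the ICER's CDF
  mod <- test_model()
  psa <- run_psa(mod, n = 400, seed = 9, scenario = "vs_noHA")
  p <- ceac(psa$draws, psa$ci_icer[1])$probability
  expect_lt(abs(p - 0.025), 0.01)
  p97 <- ceac(psa$draws, psa$ci_icer[2])$probability
  expect_lt(abs(p97 - 0.975), 0.01)
})

test_that("one-way sensitivity pins parameters and brackets the base case", {
  mod <- test_model()
  bc <- base_case(mod, "vs_noHA")$icer$icer
  ## degenerate pin at the mean reproduces the base case
  e0 <- one_way(mod, "prop_eligible", low = 0.70, high = 0.70,
                scenario = "vs_noHA")
  expect_equal(e0$icer_low, bc, tolerance = 1e-9)
  expect_equal(e0$icer_high, bc, tolerance = 1e-9)
  ## a costlier surgery strictly raises the ICER
  e1 <- one_way(mod, "c_surgery_device", low = 1, high = 1.2,
                scenario = "vs_noHA")
  expect_gt(e1$icer_high, e1$icer_low)
  expect_equal(e1$icer_low, bc, tolerance = 1e-9)
  ## default range comes from the 95% CI and brackets the base case
  e2 <- one_way(mod, "prop_eligible", scenario = "vs_noHA")
  expect_lte(min(e2$icer_low, e2$icer_high), bc)
  expect_gte(max(e2$icer_low, e2$icer_high), bc)
  expect_error(one_way(mod, "no_such_parameter"), "unknown parameter")
  expect_error(one_way(mod, "prop_eligible", low = -0.5, high = 0.9),
               "outside")
})

test_that("tornado ranks parameters and the discount sweep is ordered", {
  mod <- test_model()
  tor <- tornado(mod, parameters = c("prop_eligible", "upgrade_time_months",
                                     "p_discontinue"),
                 scenario = "vs_noHA")
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$spread) <= 0))
  ## QALY gains are long-run, so lower discount rates give lower ICERs
  sw <- discount_scenarios(mod, scenario = "vs_noHA")
  expect_equal(sw$rate, c(0.015, 0.03, 0.035, 0.05))
  expect_true(all(diff(sw$icer) > 0))
})

test_that("the convention sweep covers every flagged configuration", {
  mod <- test_model()
  sweep <- convention_sweep(mod, "vs_HA")
  expect_equal(nrow(sweep), 12)  # 2 x 2 x 3
  expect_true(all(is.finite(sweep$icer)))
  ## the hearing-aid replacement policy only moves the comparator arm cost
  base_row <- sweep$ha_replacement == "compliant" &
    !sweep$half_cycle_correction &
    sweep$failure_interpretation == "lifetime_cumulative"
  none_row <- sweep$ha_replacement == "none" &
    !sweep$half_cycle_correction &
    sweep$failure_interpretation == "lifetime_cumulative"
  expect_gt(sweep$delta_cost[none_row], sweep$delta_cost[base_row])
  expect_equal(sweep$delta_qaly[none_row], sweep$delta_qaly[base_row])
})
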