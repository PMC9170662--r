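test_that("the full internal validation battery passes on the defaults", {
  v <- validate_model(test_model(), n_draws = 30L, n_microsim = 4000L,
                      seed = 3L)
  expect_s3_class(v, "uci_validation")
  expect_true(attr(v, "all_passed"))
  expect_setequal(v$check, c("prior_mean_round_trip", "draw_admissibility",
                             "transition_row_sums", "cohort_conservation",
                             "null_effect", "extreme_mortality_cost",
                             "microsim_cross_check"))
})

test_that("an injected row-sum violation is caught", {
  m <- build_transition_matrix(2, test_mean_draw(), test_model()$life_table,
                               "UCI", "traditional",
                               config = test_model()$config)
  m["UCI_well", "UCI_well"] <- m["UCI_well", "UCI_well"] + 1e-6
  expect_error(validate_transition_matrix(m), "model invalid")
})

test_that("microsimulation reproduces the cohort engine within 3 MC SEs", {
  mod <- test_model()
  for (case in list(c("UCI", "marginal"), c("HA", "marginal"))) {
    co <- run_cohort(case[1], case[2], test_mean_draw(), mod$life_table,
                     mod$norms[[case[2]]], test_schedule(), test_utable(),
                     mod$config)
    ms <- simulate_individuals(case[1], case[2], test_mean_draw(),
                               mod$life_table, mod$norms[[case[2]]],
                               test_schedule(), test_utable(), mod$config,
                               n = 6000L, seed = 17L)
    expect_lt(abs(co$discounted_cost - ms$cost), 3 * ms$cost_se)
    expect_lt(abs(co$discounted_qaly - ms$qaly), 3 * ms$qaly_se)
  }
})

test_that("result writers produce reproducible JSON with run metadata", {
  mod <- test_model()
  bc <- base_case(mod, "vs_noHA")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_base_case(bc, mod, p1)
  write_base_case(bc, mod, p2)
  j1 <- jsonlite::read_json(p1)
  j2 <- jsonlite::read_json(p2)
  ## byte-identical apart from the timestamp
  j1$metadata$timestamp <- j2$metadata$timestamp <- NULL
  expect_identical(j1, j2)
  expect_equal(j1$difference$icer, bc$icer$icer)
  expect_match(j1$metadata$config_hash, "^[0-9a-f]{8}$")
  psa <- run_psa(mod, n = 25, seed = 4, scenario = "vs_HA")
  p3 <- withr::local_tempfile(fileext = ".json")
  write_psa_summary(psa, mod, p3)
  j3 <- jsonlite::read_json(p3)
  expect_equal(j3$n, 25L)
  expect_equal(j3$metadata$seed, 4L)
})

test_that("the config hash changes iff a model-relevant field changes", {
  cfg <- test_model()$config
  h0 <- config_hash(cfg)
  expect_identical(config_hash(cfg), h0)
  cfg2 <- cfg
  cfg2$discount_rate <- 0.015
  expect_false(identical(config_hash(cfg2), h0))
  cfg3 <- cfg
  cfg3$ha_replacement <- "none"
  expect_false(identical(config_hash(cfg3), h0))
})

test_that("strategy traces export and re-import through CSV", {
  mod <- test_model()
  r <- run_cohort("UCI", "traditional", test_mean_draw(), mod$life_table,
                  mod$norms$traditional, test_schedule(), test_utable(),
                  mod$config)
  path <- withr::local_tempfile(fileext = ".csv")
  tf <- trace_frame(r, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$UCI_well, tf$UCI_well, tolerance = 1e-12)
  expect_equal(sum(back$discounted_cost), r$discounted_cost,
               tolerance = 1e-9)
})
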