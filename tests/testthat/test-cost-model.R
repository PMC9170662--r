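test_that("resource blocks sum as the published tables do", {
  tab <- test_model()$cost_tables
  expect_equal(sum_resource_block(tab[0, ]), 0)
  block <- function(b) sum_resource_block(tab[tab$block == b, ])
  expect_equal(block("assessment"), 1822)
  expect_equal(block("surgery"), 5956 + 16964)  # 22,920
  expect_equal(block("processor"), 5000 + 1.5 * 84 + 1.5 * 96)  # 5,270
  expect_equal(block("explant"), 1.5 * 84 + 4253)
  expect_equal(block("reimplant"), 1.5 * 84 + 104 + 130 + 284 + 44 + 5956 + 31)
  expect_equal(block("year1"), 31 + 6 * 1.5 * 84 + 4.5 * 1.5 * 96)
  expect_equal(block("maintenance"), 84 + 96 + 328 + 44)
  ## row order never matters
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  class(shuffled) <- class(tab)
  expect_equal(sum_resource_block(shuffled[shuffled$block == "assessment", ]),
               1822)
  expect_error(sum_resource_block(data.frame(n_visits = 1,
                                             units_per_visit = -1,
                                             unit_cost = 5)), "negative")
})

test_that("expected short-term adverse-event cost matches the hand sum", {
  expect_equal(expected_st_ae_cost(c(a = 0, b = 0), c(a = 31, b = 41)), 0)
  sch <- test_schedule()
  expect_equal(unname(sch$one_off["st_ae_expected"]),
               0.065 * 31 + 0.194 * 31 + 0.036 * 31 + 0.015 * (31 + 10),
               tolerance = 1e-9)  # = 9.76
  expect_equal(unname(sch$one_off["st_ae_expected"]), 9.76,
               tolerance = 1e-9)
})

test_that("the cost schedule carries the derived event and cycle costs", {
  sch <- test_schedule()
  one <- sch$one_off
  expect_equal(unname(one["surgery_plus_device"]), 22920)
  expect_equal(unname(one["processor_replacement"]), 5270)
  expect_equal(unname(one["hearing_aid_pair"]), 332)
  expect_equal(unname(one["hearing_aid_single"]), 166)
  ## assessment is loaded by the eligibility proportion
  expect_equal(unname(one["pre_implant_assessment"]), 1822 / 0.70)
  rec <- sch$recurring
  ## annual maintenance 328 contributes 164 per six-month cycle from year 2
  expect_equal(unname(rec["uci_maintenance_per_cycle"]),
               (84 + 96 + 328 + 44) / 2)
  expect_equal(unname(rec["uci_maintenance_per_cycle"]) -
                 (84 + 96 + 44) / 2, 164)
  expect_equal(unname(rec["lt_ae_per_cycle"]), 31 / 2)
  expect_equal(unname(rec["uci_year1_per_cycle"]),
               (31 + 6 * 1.5 * 84 + 4.5 * 1.5 * 96) / 2)
})

test_that("doubling all unit costs doubles every schedule entry", {
  tab <- test_model()$cost_tables
  tab2 <- tab
  tab2$unit_cost <- tab2$unit_cost * 2
  sch1 <- build_cost_schedule(tab, test_mean_draw())
  sch2 <- build_cost_schedule(tab2, test_mean_draw())
  expect_equal(sch2$one_off, 2 * sch1$one_off)
  expect_equal(sch2$recurring, 2 * sch1$recurring)
})

test_that("every table block is consumed by the schedule, missing blocks fail", {
  tab <- test_model()$cost_tables
  covered <- c("assessment", "surgery", "hearing_aid", "year1", "maintenance",
               "processor", "explant", "reimplant", "ae_short_term",
               "ae_long_term")
  expect_setequal(unique(tab$block), covered)
  dropped <- tab[tab$block != "explant", ]
  class(dropped) <- class(tab)
  expect_error(build_cost_schedule(dropped, test_mean_draw()), "explant")
})

test_that("a cost schedule exports to JSON and reads back", {
  path <- withr::local_tempfile(fileext = ".json")
  write_cost_schedule(test_schedule(), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$one_off$surgery_plus_device, 22920)
  expect_equal(back$one_off$st_ae_expected, 9.76, tolerance = 1e-9)
})
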