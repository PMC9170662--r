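# Shared fixtures, built once per test run.

the <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(the$model)) the$model <- uci_model()
  the$model
}

test_mean_draw <- function() {
  if (is.null(the$draw)) the$draw <- mean_draw(test_model()$params)
  the$draw
}

test_schedule <- function() {
  if (is.null(the$schedule))
    the$schedule <- build_cost_schedule(test_model()$cost_tables,
                                        test_mean_draw())
  the$schedule
}

test_utable <- function() {
  if (is.null(the$utable))
    the$utable <- utility_table_from_draw(test_mean_draw())
  the$utable
}

# Memoised 1,000-draw PSA runs shared by the acceptance blocks.
test_psa <- function(scenario) {
  key <- paste0("psa_", scenario)
  if (is.null(the[[key]]))
    the[[key]] <- run_psa(test_model(), n = 1000L, seed = 1L,
                          scenario = scenario)
  the[[key]]
}

# A life table with constant annual mortality (terminal age still fatal),
# for closed-form oracles.
flat_life_table <- function(q_annual, min_age = 18L, max_age = 110L) {
  ages <- min_age:max_age
  q <- rep(q_annual, length(ages))
  q[length(q)] <- 1
  structure(data.frame(age = ages, q_annual = q),
            class = c("uci_life_table", "data.frame"))
}

# Independent quantile oracle: invert a CDF by bisection, never via q*().
cdf_quantile <- function(cdf, p, lower, upper) {
  stats::uniroot(function(x) cdf(x) - p, lower = lower, upper = upper,
                 tol = 1e-12)$root
}
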