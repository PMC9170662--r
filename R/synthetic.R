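#' Build a synthetic all-cause mortality life table (Gompertz-Makeham)
#'
#' The cohort model needs an age-indexed annual probability of death for the
#' general adult population. No such table ships with the published inputs, so
#' the package generates one from the Gompertz-Makeham law
#' h(x) = a + b * exp(c * x): a constant background hazard plus an
#' exponentially ageing component. The annual death probability integrates
#' the hazard over each year of age exactly:
#' q(x) = 1 - exp(-(a + (b/c) * (exp(c*(x+1)) - exp(c*x)))).
#'
#' Defaults are calibrated so that life expectancy at age 52.8 (the cohort's
#' average implantation age) is about 31 years, plausible for the UK adult
#' population; swap in a national life table CSV via [read_life_table()] for
#' exact reproduction against published mortality.
#'
#' @param makeham_a Background (age-independent) hazard per year, >= 0.
#' @param gompertz_b Baseline ageing hazard per year at age 0, > 0.
#' @param gompertz_c Exponential ageing rate per year, > 0.
#' @param max_age Terminal age; `q` is forced to 1 there.
#' @param min_age First tabulated age.
#' @return A `uci_life_table`: data.frame with columns `age`, `q_annual`.
#' @examples
#' lt <- make_life_table()
#' head(lt)
#' @export
make_life_table <- function(makeham_a = 5e-4, gompertz_b = 1.4e-5,
                            gompertz_c = 0.10, max_age = 110L,
                            min_age = 18L) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, gompertz_c > 0, max_age > 18,
            makeham_a + gompertz_b > 0)
  ages <- seq.int(min_age, max_age)
  cumhaz <- makeham_a + (gompertz_b / gompertz_c) *
    (exp(gompertz_c * (ages + 1)) - exp(gompertz_c * ages))
  q <- 1 - exp(-cumhaz)
  if (any(q[-length(q)] >= 1)) {
    warning("hazard implies q >= 1 before the terminal age; clipping")
    q <- pmin(q, 1)
  }
  q[length(q)] <- 1
  structure(data.frame(age = ages, q_annual = q),
            params = c(a = makeham_a, b = gompertz_b, c = gompertz_c),
            class = c("uci_life_table", "data.frame"))
}

#' Annual death probability at an (integer) age
#'
#' Ages beyond the table's terminal age return 1.
#'
#' @param life_table A `uci_life_table`.
#' @param age Age in years; the containing year of age is used.
#' @return Probability of death within the year of age.
#' @export
annual_mortality <- function(life_table, age) {
  idx <- findInterval(age, life_table$age)
  out <- numeric(length(age))
  out[idx < 1L] <- life_table$q_annual[1L]
  beyond <- idx >= nrow(life_table)
  out[beyond] <- 1
  inside <- idx >= 1L & !beyond
  out[inside] <- life_table$q_annual[idx[inside]]
  out
}

#' Survival curve implied by a life table
#'
#' Probability of surviving from the table's first age to each tabulated age.
#'
#' @param life_table A `uci_life_table`.
#' @return data.frame with columns `age`, `surv` (surv = 1 at the first age).
#' @export
life_table_survival <- function(life_table) {
  s <- cumprod(c(1, 1 - life_table$q_annual[-nrow(life_table)]))
  data.frame(age = life_table$age, surv = s)
}

#' Expectation of life at an age, by trapezoid integration of survival
#'
#' @param life_table A `uci_life_table`.
#' @param age Starting (integer) age.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(life_table, age) {
  i0 <- match(floor(age), life_table$age)
  if (is.na(i0)) stop("age ", age, " outside life table", call. = FALSE)
  q <- life_table$q_annual[i0:nrow(life_table)]
  s <- cumprod(c(1, 1 - q))
  sum((s[-length(s)] + s[-1]) / 2)
}

#' Read / write a life table CSV (columns `age`, `q_annual`)
#'
#' @param life_table A `uci_life_table`.
#' @param path File path.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table)[c("age", "q_annual")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  if (!file.exists(path))
    stop("life table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("age", "q_annual") %in% names(df)))
    stop("life table ", path, " must have columns age, q_annual",
         call. = FALSE)
  if (any(df$q_annual < 0 | df$q_annual > 1))
    stop("life table ", path, " has q_annual outside [0,1]", call. = FALSE)
  df <- df[order(df$age), ]
  df$q_annual[nrow(df)] <- 1
  structure(df, class = c("uci_life_table", "data.frame"))
}

#' Build a population utility-norm curve declining linearly with age
#'
#' Utilities in the model age with the general population: the norm value at
#' the cohort's start age anchors the curve (baseline utility + reported
#' decrement from the norm), and the curve declines linearly thereafter,
#' clamped to [0, 1]:
#' norm(age) = clamp(anchor - decline_per_decade * (age - anchor_age)/10).
#'
#' @param anchor_age Age (years) at which the anchor value applies.
#' @param anchor_value Population norm utility at the anchor age, in (0, 1].
#' @param decline_per_decade Utility lost per decade of ageing, >= 0.
#' @return A function `norm(age)` vectorized over age, carrying its
#'   parameters as attributes; class `uci_norm_curve`.
#' @examples
#' norm <- make_norm_curve(52.8, 0.849, 0.03)
#' norm(c(52.8, 82.8))
#' @export
make_norm_curve <- function(anchor_age, anchor_value,
                            decline_per_decade = 0.03) {
  stopifnot(anchor_value > 0, anchor_value <= 1, decline_per_decade >= 0)
  f <- function(age) {
    pmin(pmax(anchor_value - decline_per_decade * (age - anchor_age) / 10,
              0), 1)
  }
  structure(f, anchor_age = anchor_age, anchor_value = anchor_value,
            decline_per_decade = decline_per_decade,
            class = c("uci_norm_curve", "function"))
}

#' Tabulate / read a norm curve as CSV (columns `age`, `norm`)
#'
#' `read_norm_curve()` returns a step-interpolating `uci_norm_curve` over the
#' tabulated ages (linear interpolation between grid points).
#'
#' @param norm A `uci_norm_curve`.
#' @param path File path.
#' @param ages Ages at which to tabulate.
#' @export
write_norm_curve <- function(norm, path, ages = 18:110) {
  utils::write.csv(data.frame(age = ages, norm = norm(ages)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_norm_curve
#' @export
read_norm_curve <- function(path) {
  if (!file.exists(path))
    stop("norm curve file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("age", "norm") %in% names(df)))
    stop("norm curve ", path, " must have columns age, norm", call. = FALSE)
  f <- function(age) {
    pmin(pmax(stats::approx(df$age, df$norm, xout = age, rule = 2)$y, 0), 1)
  }
  structure(f, anchor_age = df$age[1L], anchor_value = df$norm[1L],
            decline_per_decade = NA_real_,
            class = c("uci_norm_curve", "function"))
}

#' Simulate individual lifespans from a life table
#'
#' Used by the validation battery to check the life table's internal
#' consistency (simulated mean lifespan vs trapezoid expectation of life).
#'
#' @param life_table A `uci_life_table`.
#' @param n Number of individuals.
#' @param start_age Starting integer age.
#' @param seed Integer seed.
#' @return Numeric vector of years lived beyond `start_age`.
#' @export
simulate_lifespans <- function(life_table, n, start_age, seed = 1L) {
  i0 <- match(floor(start_age), life_table$age)
  q <- life_table$q_annual[i0:nrow(life_table)]
  s <- cumprod(1 - q)                    # P(survive >= k+1 whole years)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  u <- stats::runif(n)
  ## death in year k (0-based) when s[k] < u <= s[k-1]; uniform within year
  yr <- findInterval(-u, -c(1, s)) - 1L  # number of whole years survived
  yr + stats::runif(n)
}
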