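#' Define a single model parameter
#'
#' A parameter is described the way decision-model input tables report them:
#' a mean, an optional 95\% confidence interval, and a prior distribution
#' family used for probabilistic sensitivity analysis. Probabilities and
#' utilities take `beta` priors, positive times and costs take `gamma`
#' priors, and structural constants (ages, rates fixed by guideline) are
#' `fixed`.
#'
#' @param name Parameter identifier (unique within a set).
#' @param mean Point estimate (the value used in the deterministic base case).
#' @param ci_low,ci_high Limits of the 95\% confidence interval, or `NA` for
#'   fixed parameters.
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param units Free-text units label (e.g. `"probability"`, `"months"`).
#' @param ci_assumed Logical; `TRUE` when the interval is an analyst
#'   assumption rather than a reported interval.
#' @return A one-row `data.frame` with class `uci_parameter_spec`.
#' @export
parameter_spec <- function(name, mean, ci_low = NA_real_, ci_high = NA_real_,
                           family = c("beta", "gamma", "fixed"),
                           units = "", ci_assumed = FALSE) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, is.numeric(mean))
  if (family != "fixed") {
    if (is.na(ci_low) || is.na(ci_high))
      stop("parameter '", name, "': family '", family, "' requires a 95% CI",
           call. = FALSE)
    if (!(ci_low <= mean && mean <= ci_high))
      stop("parameter '", name, "': mean ", mean,
           " lies outside its CI (", ci_low, ", ", ci_high, ")", call. = FALSE)
  }
  if (family == "beta") {
    if (ci_low < 0 || ci_high > 1 || mean <= 0 || mean >= 1)
      stop("parameter '", name, "': beta family requires mean in (0,1) and ",
           "CI within [0,1]", call. = FALSE)
  }
  if (family == "gamma" && (ci_low <= 0 || mean <= 0))
    stop("parameter '", name, "': gamma family requires positive mean and ",
         "ci_low > 0", call. = FALSE)
  out <- data.frame(name = name, mean = mean, ci_low = ci_low,
                    ci_high = ci_high, family = family, units = units,
                    ci_assumed = ci_assumed, stringsAsFactors = FALSE)
  class(out) <- c("uci_parameter_spec", class(out))
  out
}

#' Assemble parameter specifications into a parameter set
#'
#' @param ... `parameter_spec()` rows (or data.frames of them).
#' @return A `uci_parameter_set`: a data.frame of specs, unfitted.
#' @seealso [fit_parameter_set()], [sample_draw()]
#' @export
parameter_set <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  if (anyDuplicated(df$name))
    stop("duplicate parameter names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  rownames(df) <- df$name
  class(df) <- c("uci_parameter_set", "data.frame")
  df
}

#' Fit a beta distribution to a mean and 95\% CI
#'
#' Holds the mean exactly (shape1 = mean * kappa, shape2 = (1 - mean) * kappa)
#' and searches over the concentration kappa for the distribution whose 2.5\%
#' and 97.5\% quantiles best match the reported interval in least squares.
#' Wide, near-uniform intervals cannot always be matched exactly; the best
#' least-squares fit is returned and the achieved quantiles reported in the
#' `achieved_ci` attribute.
#'
#' @param mean Mean in (0, 1).
#' @param ci_low,ci_high Reported 95\% CI limits, in [0, 1].
#' @param name Parameter name used in error messages.
#' @return Numeric vector `c(shape1, shape2)` with attribute `achieved_ci`.
#' @examples
#' fit_beta_from_mean_ci(0.70, 0.372, 0.938)
#' @export
fit_beta_from_mean_ci <- function(mean, ci_low, ci_high, name = "parameter") {
  if (!(mean > 0 && mean < 1))
    stop("parameter '", name, "': beta mean must lie in (0,1)", call. = FALSE)
  if (!(ci_low >= 0 && ci_high <= 1 && ci_low < ci_high))
    stop("parameter '", name, "': invalid beta CI (", ci_low, ", ", ci_high,
         ")", call. = FALSE)
  if (mean < ci_low || mean > ci_high)
    stop("parameter '", name, "': mean ", mean, " outside CI (", ci_low,
         ", ", ci_high, ")", call. = FALSE)
  obj <- function(logk) {
    k <- exp(logk)
    a <- mean * k
    b <- (1 - mean) * k
    (stats::qbeta(0.025, a, b) - ci_low)^2 +
      (stats::qbeta(0.975, a, b) - ci_high)^2
  }
  opt <- stats::optimize(obj, interval = c(log(1e-2), log(1e7)), tol = 1e-12)
  k <- exp(opt$minimum)
  shapes <- c(shape1 = mean * k, shape2 = (1 - mean) * k)
  attr(shapes, "achieved_ci") <-
    stats::qbeta(c(0.025, 0.975), shapes[1L], shapes[2L])
  shapes
}

#' Fit a gamma distribution to a mean and 95\% CI
#'
#' Holds the mean exactly (scale = mean / shape) and searches over the shape
#' for the best least-squares match of the 2.5\% and 97.5\% quantiles to the
#' reported interval.
#'
#' @inheritParams fit_beta_from_mean_ci
#' @return Numeric vector `c(shape, scale)` with attribute `achieved_ci`.
#' @examples
#' fit_gamma_from_mean_ci(106, 29, 232)  # months to sound processor upgrade
#' @export
fit_gamma_from_mean_ci <- function(mean, ci_low, ci_high, name = "parameter") {
  if (!(ci_low > 0 && mean > ci_low && ci_high > mean))
    stop("parameter '", name, "': gamma fit requires 0 < ci_low < mean < ",
         "ci_high; got (", ci_low, ", ", mean, ", ", ci_high, ")",
         call. = FALSE)
  obj <- function(logshape) {
    sh <- exp(logshape)
    sc <- mean / sh
    (stats::qgamma(0.025, shape = sh, scale = sc) - ci_low)^2 +
      (stats::qgamma(0.975, shape = sh, scale = sc) - ci_high)^2
  }
  opt <- stats::optimize(obj, interval = c(log(1e-3), log(1e6)), tol = 1e-12)
  sh <- exp(opt$minimum)
  out <- c(shape = sh, scale = mean / sh)
  attr(out, "achieved_ci") <-
    stats::qgamma(c(0.025, 0.975), shape = sh, scale = out[2L])
  out
}

#' Fit prior distributions for every non-fixed parameter in a set
#'
#' @param params A `uci_parameter_set`.
#' @return The set with columns `par1`, `par2` filled in (beta: shape1/shape2;
#'   gamma: shape/scale; fixed: `NA`) and class `uci_parameter_set` retained.
#' @export
fit_parameter_set <- function(params) {
  stopifnot(inherits(params, "uci_parameter_set"))
  params$par1 <- NA_real_
  params$par2 <- NA_real_
  for (i in seq_len(nrow(params))) {
    fam <- params$family[i]
    if (fam == "fixed") next
    fit <- if (fam == "beta") {
      fit_beta_from_mean_ci(params$mean[i], params$ci_low[i],
                            params$ci_high[i], name = params$name[i])
    } else {
      fit_gamma_from_mean_ci(params$mean[i], params$ci_low[i],
                             params$ci_high[i], name = params$name[i])
    }
    params$par1[i] <- fit[1L]
    params$par2[i] <- fit[2L]
  }
  attr(params, "fitted") <- TRUE
  params
}

## Counter-based substream key: every (root seed, draw, parameter) triple maps
## to its own RNG seed, so draw k is identical whether or not draws 1..k-1
## were ever generated, and adding a parameter does not shift the others.
## The parameter stride exceeds any realistic parameter count; draws up to
## 10^6 stay collision-free within one root seed.
.substream_seed <- function(seed, draw_id, param_index) {
  as.integer((as.double(seed) %% 2147483647 + 2099 * as.double(draw_id) +
                50331653 * as.double(param_index)) %% 2147483647)
}

.substream_uniform <- function(seed, draw_id, param_index) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substream_seed(seed, draw_id, param_index))
  stats::runif(1L)
}

#' Draw one realization of all parameters
#'
#' Fixed parameters return their mean. Each non-fixed parameter is drawn by
#' inverting its fitted beta or gamma CDF at a uniform variate keyed on
#' (seed, draw_id, parameter position), so identical `(seed, draw_id)` pairs
#' are bit-identical and draws are order-independent.
#'
#' @param params A fitted `uci_parameter_set` (see [fit_parameter_set()]).
#' @param draw_id Positive integer index of the draw; `draw_id = 0` is
#'   reserved for the deterministic draw (all parameters at their mean).
#' @param seed Root integer seed.
#' @return A `uci_parameter_draw`: named list of values with attributes
#'   `draw_id` and `seed`.
#' @export
sample_draw <- function(params, draw_id, seed) {
  stopifnot(inherits(params, "uci_parameter_set"))
  if (!isTRUE(attr(params, "fitted")) && draw_id != 0 &&
      any(params$family != "fixed"))
    stop("parameter set is unfitted: call fit_parameter_set() first",
         call. = FALSE)
  vals <- numeric(nrow(params))
  names(vals) <- params$name
  for (i in seq_len(nrow(params))) {
    fam <- params$family[i]
    if (fam == "fixed" || draw_id == 0L) {
      vals[i] <- params$mean[i]
    } else {
      if (is.na(params$par1[i]))
        stop("parameter '", params$name[i], "' has no fitted distribution",
             call. = FALSE)
      u <- .substream_uniform(seed, draw_id, i)
      vals[i] <- if (fam == "beta") {
        stats::qbeta(u, params$par1[i], params$par2[i])
      } else {
        stats::qgamma(u, shape = params$par1[i], scale = params$par2[i])
      }
    }
  }
  structure(as.list(vals), draw_id = draw_id, seed = seed,
            class = "uci_parameter_draw")
}

#' Deterministic draw: every parameter at its mean
#'
#' @inheritParams sample_draw
#' @return A `uci_parameter_draw` with `draw_id = 0`.
#' @export
mean_draw <- function(params) sample_draw(params, draw_id = 0L, seed = 0L)

#' @export
print.uci_parameter_set <- function(x, ...) {
  cat("Model parameter set:", nrow(x), "parameters (",
      sum(x$family == "beta"), "beta,", sum(x$family == "gamma"), "gamma,",
      sum(x$family == "fixed"), "fixed )\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read / write a parameter set as CSV
#'
#' The CSV carries the columns `name, mean, ci_low, ci_high, family, units,
#' ci_assumed`; fitted shapes are recomputed on read.
#'
#' @param params A `uci_parameter_set`.
#' @param path File path.
#' @return `read_parameter_set()` returns an (unfitted) `uci_parameter_set`.
#' @export
write_parameter_set <- function(params, path) {
  utils::write.csv(
    as.data.frame(params)[c("name", "mean", "ci_low", "ci_high", "family",
                            "units", "ci_assumed")],
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mean", "ci_low", "ci_high", "family", "units")
  if (!all(need %in% names(df)))
    stop("parameter file ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (is.null(df$ci_assumed)) df$ci_assumed <- FALSE
  do.call(parameter_set, lapply(seq_len(nrow(df)), function(i)
    parameter_spec(df$name[i], df$mean[i], df$ci_low[i], df$ci_high[i],
                   family = df$family[i], units = df$units[i],
                   ci_assumed = as.logical(df$ci_assumed[i]))))
}
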