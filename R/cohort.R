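#' Run the deterministic Markov cohort trace
#'
#' Propagates a cohort that starts in the `initial` state at `start_age`
#' through one treatment cycle (the initial/perioperative year, carrying
#' procedure-related and background mortality) followed by `n_cycles`
#' one-year Markov follow-up cycles, so the model horizon is
#' `n_cycles + 1` years. Background mortality and 90-day lobectomy
#' mortality age with the cohort: cycle `t` uses the curves at attained age
#' `start_age + t - 1`. The run is fully deterministic.
#'
#' @param arm `"lobectomy"` or `"sabr"`.
#' @param start_age Age at diagnosis, in `[45, 85]`.
#' @param params A `lung_params` object; defaults to the packaged base case.
#' @return An object of class `cohort_trace`: a list with the occupancy
#'   matrix (`horizon + 1` rows, cycle 0 is the point mass on `initial`),
#'   the `alive` fraction per cycle boundary, attained ages, and the inputs.
#' @examples
#' tr <- run_cohort("lobectomy", 45)
#' life_expectancy(tr)
#' survival_at(tr, 5)
#' @export
run_cohort <- function(arm = c("lobectomy", "sabr"), start_age,
                       params = default_params()) {
  arm <- match.arg(arm)
  validate_params(params)
  .check_salvage_dm(params)
  if (!is.numeric(start_age) || length(start_age) != 1L ||
      start_age < 45 || start_age > 85)
    stop("'start_age' must be in [45, 85]", call. = FALSE)
  states <- health_states(arm)
  ns <- nrow(states)
  n <- as.integer(params$n_cycles) + 1L  # treatment cycle + follow-up
  ages <- start_age + seq_len(n) - 1
  bg <- eval_age_curve(params$bg_mortality, ages)
  ml <- eval_age_curve(params$mort_lobectomy, ages)
  pts <- .param_points(params)
  occ <- matrix(0, n + 1L, ns,
                dimnames = list(cycle = 0:n, state = states$name))
  occ[1L, 1L] <- 1
  v <- occ[1L, ]
  for (t in seq_len(n)) {
    v <- v %*% .trans_matrix(arm, pts, bg[t], ml[t])
    occ[t + 1L, ] <- v
  }
  structure(list(
    arm = arm,
    start_age = start_age,
    occupancy = occ,
    alive = as.numeric(1 - occ[, "death"]),
    attained_age = start_age + 0:n,
    horizon = n,
    states = states,
    params = params
  ), class = "cohort_trace")
}

#' Life expectancy of a cohort trace
#'
#' Half-cycle-corrected life expectancy over the model horizon: under the
#' assumption that each transition happens halfway through its cycle, the
#' expected life years are the trapezoidal sum
#' `0.5 S(0) + S(1) + ... + S(n-1) + 0.5 S(n)` of the alive fraction.
#' Bounded above by the horizon; no tail beyond it is added.
#'
#' @param trace A `cohort_trace`.
#' @return Life expectancy in years.
#' @export
life_expectancy <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  s <- trace$alive
  n <- length(s)
  sum((s[-1] + s[-n]) / 2) * trace$params$cycle_length
}

#' Overall survival at a time point
#'
#' Reads the alive fraction of the trace at time `t` years after diagnosis.
#' Integer times read the trace directly; non-integer times interpolate
#' linearly between cycle boundaries.
#'
#' @param trace A `cohort_trace`.
#' @param t Time(s) in years, within `[0, horizon]`.
#' @return Survival probabilities in `[0, 1]`.
#' @export
survival_at <- function(trace, t) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > trace$horizon))
    stop(sprintf("'t' must lie within the model horizon [0, %d]",
                 trace$horizon), call. = FALSE)
  stats::approx(0:trace$horizon, trace$alive, xout = t)$y
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Markov cohort trace: %s arm, age %g at diagnosis, %d-year horizon\n",
              x$arm, x$start_age, x$horizon))
  cat(sprintf("  life expectancy: %.2f years\n", life_expectancy(x)))
  cat(sprintf("  5-year overall survival: %.1f%%\n",
              100 * survival_at(x, min(5, x$horizon))))
  invisible(x)
}

#' @export
summary.cohort_trace <- function(object, ...) {
  out <- list(
    arm = object$arm,
    start_age = object$start_age,
    horizon = object$horizon,
    life_expectancy = life_expectancy(object),
    survival = data.frame(year = 0:object$horizon, os = object$alive)
  )
  class(out) <- "summary.cohort_trace"
  out
}

#' @export
print.summary.cohort_trace <- function(x, ...) {
  cat(sprintf("%s arm, age %g at diagnosis\n", x$arm, x$start_age))
  cat(sprintf("Life expectancy over a %d-year horizon: %.2f years\n",
              x$horizon, x$life_expectancy))
  cat("Overall survival by year:\n")
  print(transform(x$survival, os = round(os, 4)), row.names = FALSE)
  invisible(x)
}

#' Cohort trace as a data frame
#'
#' One row per cycle boundary; columns are the state occupancies plus
#' `alive` and `attained_age`.
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  df <- as.data.frame(x$occupancy)
  df <- cbind(cycle = 0:x$horizon, df)
  df$alive <- x$alive
  df$attained_age <- x$attained_age
  rownames(df) <- NULL
  df
}

#' Predicted survival from a cohort trace
#'
#' @param object A `cohort_trace`.
#' @param t Times (years) at which to predict overall survival; defaults to
#'   every cycle boundary.
#' @param ... Unused.
#' @return Numeric vector of survival probabilities.
#' @export
predict.cohort_trace <- function(object, t = 0:object$horizon, ...) {
  survival_at(object, t)
}

#' Simulate individual patients from a cohort model
#'
#' First-order microsimulation draw using the trace's arm, start age and
#' parameters; see [microsimulate()].
#'
#' @param object A `cohort_trace`.
#' @param nsim Number of virtual patients.
#' @param seed Integer seed (required for reproducibility).
#' @param ... Unused.
#' @return A `microsim_result`.
#' @export
simulate.cohort_trace <- function(object, nsim = 10000, seed, ...) {
  microsimulate(object$arm, object$start_age, object$params,
                n_patients = nsim, seed = seed)
}

#' @export
plot.cohort_trace <- function(x, col = "black", lwd = 2, add = FALSE, ...) {
  if (add) {
    graphics::lines(0:x$horizon, x$alive, col = col, lwd = lwd, ...)
  } else {
    graphics::plot(0:x$horizon, x$alive, type = "l", col = col, lwd = lwd,
                   xlab = "Years since diagnosis", ylab = "Overall survival",
                   ylim = c(0, 1),
                   main = sprintf("%s, age %g", x$arm, x$start_age), ...)
  }
  invisible(x)
}

# base-case life-expectancy difference (lobectomy minus SABR), shared by the
# sensitivity module
.le_diff <- function(start_age, params) {
  life_expectancy(run_cohort("lobectomy", start_age, params)) -
    life_expectancy(run_cohort("sabr", start_age, params))
}
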