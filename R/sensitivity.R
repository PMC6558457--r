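# which arm(s) a point parameter feeds into (mort_lobectomy also enters the
# SABR arm through salvage lobectomy for local recurrence)
.param_arm <- function(param) {
  switch(param,
    mort_sabr = "sabr",
    p_prog_lob = , frac_lr_lob = , frac_rr_lob = , p_salv_rr_lob = ,
    p_prog_post_salv_rr_lob = , p_pn_positive = "lobectomy",
    p_prog_sabr = , frac_lr_sabr = , frac_rr_sabr = , p_salv_lr_sabr = ,
    p_salv_rr_sabr = , p_prog_post_salv_lr_sabr = ,
    p_prog_post_salv_rr_sabr = "sabr",
    "both")
}

.set_point <- function(params, param, value) {
  e <- params[[param]]
  e$point <- value
  if (e$low > value) e$low <- value
  if (e$high < value) e$high <- value
  params[[param]] <- e
  params
}

.check_sens_param <- function(params, param) {
  if (!param %in% .estimate_fields)
    stop(sprintf(
      "'%s' is not a point(range) parameter; one-way/threshold/two-way %s",
      param, "analyses vary the point estimates only"), call. = FALSE)
  invisible(params[[param]])
}

#' One-way sensitivity of the life-expectancy difference
#'
#' Evaluates the base-case deterministic life-expectancy difference
#' (lobectomy minus SABR) at the low and high ends of one parameter's
#' reported range, all other parameters fixed at base case.
#'
#' @param param Name of a point(range) parameter (see `tornado()` for the
#'   full set).
#' @param start_age Age at diagnosis.
#' @param params Base `lung_params`.
#' @return Object of class `tornado_entry`: a one-row data frame with
#'   `parameter`, `low_input`, `high_input`, `le_diff_at_low`,
#'   `le_diff_at_high`, `width`, `degenerate`.
#' @examples
#' one_way("p_prog_lob", 75, default_params())
#' @export
one_way <- function(param, start_age, params = default_params()) {
  est <- .check_sens_param(params, param)
  base_diff <- .le_diff(start_age, params)
  if (is_degenerate(est)) {
    out <- data.frame(parameter = param, low_input = est$low,
                      high_input = est$high, le_diff_at_low = base_diff,
                      le_diff_at_high = base_diff, width = 0,
                      degenerate = TRUE)
  } else {
    d_lo <- .le_diff(start_age, .set_point(params, param, est$low))
    d_hi <- .le_diff(start_age, .set_point(params, param, est$high))
    out <- data.frame(parameter = param, low_input = est$low,
                      high_input = est$high, le_diff_at_low = d_lo,
                      le_diff_at_high = d_hi, width = abs(d_hi - d_lo),
                      degenerate = FALSE)
  }
  out$base_diff <- base_diff
  class(out) <- c("tornado_entry", "data.frame")
  out
}

#' Tornado diagram of one-way sensitivities
#'
#' Runs [one_way()] for every point(range) parameter and ranks the bars by
#' width. Parameters with degenerate ranges produce zero-width bars and are
#' flagged. The two mortality-by-age schedules are not varied: their
#' printed spreads describe variation with age, not parameter uncertainty.
#'
#' @param start_age Age at diagnosis.
#' @param params Base `lung_params`.
#' @param parameters Character vector of parameters to vary; defaults to
#'   all point(range) parameters.
#' @return Object of class `tornado`: a data frame of [one_way()] entries
#'   sorted by decreasing bar width, with the base-case difference as an
#'   attribute.
#' @examples
#' \donttest{
#' tor <- tornado(75)
#' plot(tor)
#' }
#' @export
tornado <- function(start_age, params = default_params(),
                    parameters = setdiff(.estimate_fields, "p_pn_positive")) {
  entries <- lapply(parameters, one_way, start_age = start_age,
                    params = params)
  out <- do.call(rbind, lapply(entries, as.data.frame))
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
plot.tornado <- function(x, ...) {
  y <- x[!x$degenerate, ]
  y <- y[order(y$width), ]
  lo <- pmin(y$le_diff_at_low, y$le_diff_at_high)
  hi <- pmax(y$le_diff_at_low, y$le_diff_at_high)
  base <- y$base_diff[1]
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(y) + 0.5),
                 yaxt = "n", ylab = "",
                 xlab = "LE difference, lobectomy - SABR (years)",
                 main = "One-way sensitivity")
  graphics::rect(lo, seq_len(nrow(y)) - 0.35, hi, seq_len(nrow(y)) + 0.35,
                 col = "grey70")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(y)), labels = y$parameter, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}

#' Threshold (crossover) analysis by bisection
#'
#' Finds the value of one parameter at which the two arms' base-case life
#' expectancies are equal, i.e. the root of the life-expectancy difference
#' as a function of the parameter, by bisection over a bracket. If the
#' difference does not change sign over the bracket, the preferred strategy
#' is unchanged over the whole range and a "no threshold in range" result
#' is returned rather than an error.
#'
#' @param param Name of a point(range) parameter.
#' @param start_age Age at diagnosis.
#' @param params Base `lung_params`.
#' @param bracket Length-2 numeric search interval; defaults to the
#'   parameter's reported (low, high) range.
#' @param tol Bisection tolerance on the parameter scale.
#' @return Object of class `threshold_result`: list with `parameter`,
#'   `found`, `root` (`NA` if no sign change), `bracket`, `tolerance`,
#'   `diff_at_root`, `diff_low`, `diff_high`.
#' @examples
#' \donttest{
#' find_threshold("p_prog_lob", 75)
#' }
#' @export
find_threshold <- function(param, start_age, params = default_params(),
                           bracket = NULL, tol = 1e-4) {
  est <- .check_sens_param(params, param)
  if (is.null(bracket)) bracket <- c(est$low, est$high)
  if (length(bracket) != 2L || bracket[1] >= bracket[2])
    stop("'bracket' must be an increasing length-2 interval", call. = FALSE)
  f <- function(x) .le_diff(start_age, .set_point(params, param, x))
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  base <- list(parameter = param, bracket = bracket, tolerance = tol,
               diff_low = f_lo, diff_high = f_hi, age = start_age)
  if (sign(f_lo) == sign(f_hi))
    return(structure(c(base, list(found = FALSE, root = NA_real_,
                                  diff_at_root = NA_real_)),
                     class = "threshold_result"))
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (f_mid == 0) { lo <- hi <- mid; f_lo <- f_mid; break }
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid }
    else { hi <- mid; f_hi <- f_mid }
  }
  root <- (lo + hi) / 2
  structure(c(base, list(found = TRUE, root = root,
                         diff_at_root = f(root))),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$found) {
    cat(sprintf(
      "threshold for '%s' at age %g: %.4f (LE difference %.2g years)\n",
      x$parameter, x$age, x$root, x$diff_at_root))
  } else {
    cat(sprintf(
      "no threshold for '%s' in (%.4f, %.4f) at age %g: %s preferred throughout\n",
      x$parameter, x$bracket[1], x$bracket[2], x$age,
      if (x$diff_low > 0) "lobectomy" else "SABR"))
  }
  invisible(x)
}

#' Two-way sensitivity analysis
#'
#' Maps the preferred strategy (by sign of the base-case deterministic
#' life-expectancy difference) over a grid of two parameters, each varied
#' over its reported range. Cells whose absolute difference is below
#' `tie_tol` years are labelled `"tie"`. When the two parameters feed
#' disjoint arms the grid is assembled from one-dimensional sweeps of each
#' arm, which makes the default 101-point grids cheap.
#'
#' @param param_a,param_b Names of point(range) parameters.
#' @param start_age Age at diagnosis.
#' @param params Base `lung_params`.
#' @param n_grid Grid points per axis.
#' @param a_values,b_values Optional explicit grids (override `n_grid`).
#' @param tie_tol Tie tolerance in years.
#' @return Object of class `two_way_grid`: list with `param_a`, `param_b`,
#'   `a_values`, `b_values`, `le_diff` (matrix, a by b) and `preferred`
#'   (character matrix: `"lobectomy"`, `"sabr"` or `"tie"`).
#' @examples
#' \donttest{
#' tw <- two_way("p_prog_lob", "p_prog_sabr", 75, n_grid = 21)
#' plot(tw)
#' }
#' @export
two_way <- function(param_a, param_b, start_age,
                    params = default_params(), n_grid = 101,
                    a_values = NULL, b_values = NULL, tie_tol = 1e-6) {
  ea <- .check_sens_param(params, param_a)
  eb <- .check_sens_param(params, param_b)
  if (param_a == param_b) stop("parameters must differ", call. = FALSE)
  if (is.null(a_values)) a_values <- seq(ea$low, ea$high, length.out = n_grid)
  if (is.null(b_values)) b_values <- seq(eb$low, eb$high, length.out = n_grid)
  arms_a <- .param_arm(param_a)
  arms_b <- .param_arm(param_b)
  le_arm <- function(arm, q) life_expectancy(run_cohort(arm, start_age, q))
  if (all(c(arms_a, arms_b) %in% c("lobectomy", "sabr")) && arms_a != arms_b) {
    # separable: each axis touches one arm only
    le_a <- vapply(a_values, function(v)
      le_arm(arms_a, .set_point(params, param_a, v)), 0)
    le_b <- vapply(b_values, function(v)
      le_arm(arms_b, .set_point(params, param_b, v)), 0)
    if (arms_a == "lobectomy") {
      diff <- outer(le_a, le_b, `-`)
    } else {
      diff <- -outer(le_a, le_b, `-`)
    }
  } else {
    diff <- matrix(NA_real_, length(a_values), length(b_values))
    for (i in seq_along(a_values)) {
      qa <- .set_point(params, param_a, a_values[i])
      for (j in seq_along(b_values)) {
        q <- .set_point(qa, param_b, b_values[j])
        diff[i, j] <- .le_diff(start_age, q)
      }
    }
  }
  preferred <- ifelse(abs(diff) <= tie_tol, "tie",
                      ifelse(diff > 0, "lobectomy", "sabr"))
  structure(list(param_a = param_a, param_b = param_b,
                 a_values = a_values, b_values = b_values,
                 le_diff = diff, preferred = preferred, age = start_age),
            class = "two_way_grid")
}

#' @export
print.two_way_grid <- function(x, ...) {
  tab <- table(factor(x$preferred, c("lobectomy", "sabr", "tie")))
  cat(sprintf("two-way sensitivity at age %g: %s x %s (%d x %d grid)\n",
              x$age, x$param_a, x$param_b,
              length(x$a_values), length(x$b_values)))
  cat(sprintf("  preferred: lobectomy %d cells, SABR %d, tie %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
plot.two_way_grid <- function(x, ...) {
  z <- (x$preferred == "lobectomy") + 0.5 * (x$preferred == "tie")
  graphics::image(x$a_values, x$b_values, z,
                  col = c("grey85", "grey60", "grey35"),
                  xlab = x$param_a, ylab = x$param_b,
                  main = sprintf(
                    "Preferred strategy at age %g (dark: lobectomy)", x$age),
                  ...)
  invisible(x)
}
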