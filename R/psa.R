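#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' Runs the virtual trial's parameter-uncertainty analysis for one age
#' stratum. Every uncertain point(range) probability is given a sampling
#' distribution by [fit_psa_distribution()] (degenerate estimates stay
#' fixed; the two mortality-by-age schedules describe age variation, not
#' parameter uncertainty, and are never drawn). Per iteration one joint
#' draw is taken and shared by both arms (parameters common to the arms see
#' the same value, which is what keeps prognostic factors identical across
#' arms), both arms are then evaluated deterministically with
#' [run_cohort()], and the difference in life expectancy (lobectomy minus
#' SABR) is recorded.
#'
#' The summary reports the mean difference, the 2.5/97.5 empirical
#' percentiles of the per-iteration differences, and two two-sided p-values
#' for the null of no difference: `p_normal`, the normal approximation from
#' the mean and standard deviation of the differences, and `p_empirical`,
#' twice the smaller empirical tail `2 min(P(diff <= 0), P(diff >= 0))`.
#'
#' @param start_age Age at diagnosis, in `[45, 85]`.
#' @param params Base `lung_params` whose ranges define the distributions.
#' @param n_iter Number of second-order iterations (default 10000).
#' @param seed Integer seed; required, recorded in the result.
#' @return Object of class `psa_result` with fields `age`, `n_iter`,
#'   `le_lob`, `le_sabr` (per-iteration life expectancies), `mean_diff`,
#'   `ci_low`, `ci_high`, `p_value` (the normal approximation),
#'   `p_empirical`, `sd_diff`, `seed`, `draws` (the parameter draw matrix).
#' @examples
#' \donttest{
#' ps <- run_psa(75, default_params(), n_iter = 200, seed = 1)
#' summary(ps)
#' }
#' @export
run_psa <- function(start_age, params = default_params(), n_iter = 10000,
                    seed) {
  validate_params(params)
  if (n_iter < 2) stop("'n_iter' must be >= 2", call. = FALSE)
  dists <- lapply(params[.estimate_fields], fit_psa_distribution)
  draws <- with_seed(seed, {
    d <- vapply(.estimate_fields,
                function(f) sample_psa_distribution(dists[[f]], n_iter),
                numeric(n_iter))
    # the distant fraction is the complement of the local/regional split:
    # redraw the rare joint draws whose fractions exceed 1
    for (arm in c("lob", "sabr")) {
      lr <- paste0("frac_lr_", arm); rr <- paste0("frac_rr_", arm)
      bad <- which(d[, lr] + d[, rr] > 1)
      while (length(bad)) {
        d[bad, lr] <- sample_psa_distribution(dists[[lr]], length(bad))
        d[bad, rr] <- sample_psa_distribution(dists[[rr]], length(bad))
        bad <- bad[d[bad, lr] + d[bad, rr] > 1]
      }
    }
    d
  })
  le_lob <- le_sabr <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    q <- .apply_draw(params, draws[i, ])
    le_lob[i] <- life_expectancy(run_cohort("lobectomy", start_age, q))
    le_sabr[i] <- life_expectancy(run_cohort("sabr", start_age, q))
  }
  diff <- le_lob - le_sabr
  m <- mean(diff)
  s <- stats::sd(diff)
  if (s == 0) {
    if (abs(m) < 1e-12) {
      warning("all PSA draws identical and arms tie; p-value reported as 1",
              call. = FALSE)
      p_norm <- p_emp <- 1
    } else {
      stop("degenerate PSA draws with a nonzero difference", call. = FALSE)
    }
  } else {
    p_norm <- 2 * stats::pnorm(-abs(m) / s)
    p_emp <- min(1, 2 * min(mean(diff <= 0), mean(diff >= 0)))
  }
  ci <- unname(stats::quantile(diff, c(0.025, 0.975)))
  structure(list(age = start_age, n_iter = as.integer(n_iter),
                 le_lob = le_lob, le_sabr = le_sabr,
                 mean_diff = m, sd_diff = s,
                 ci_low = ci[1], ci_high = ci[2],
                 p_value = p_norm, p_empirical = p_emp,
                 seed = as.integer(seed), draws = draws),
            class = "psa_result")
}

# replace point estimates by a named draw vector, keeping ranges consistent
.apply_draw <- function(params, draw) {
  for (f in names(draw)) {
    e <- params[[f]]
    e$point <- draw[[f]]
    if (e$low > e$point) e$low <- e$point
    if (e$high < e$point) e$high <- e$point
    params[[f]] <- e
  }
  params
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "second-order Monte Carlo PSA: age %g, %d iterations (seed %d)\n",
    x$age, x$n_iter, x$seed))
  cat(sprintf(
    "  LE difference (lobectomy - SABR): %.2f years, 95%% CI %.2f to %.2f\n",
    x$mean_diff, x$ci_low, x$ci_high))
  cat(sprintf("  p = %.4f (normal), %.4f (empirical tail)\n",
              x$p_value, x$p_empirical))
  invisible(x)
}

#' @export
summary.psa_result <- function(object, ...) {
  data.frame(age = object$age, n_iter = object$n_iter,
             le_lob = mean(object$le_lob), le_sabr = mean(object$le_sabr),
             mean_diff = object$mean_diff, sd_diff = object$sd_diff,
             ci_low = object$ci_low, ci_high = object$ci_high,
             p_normal = object$p_value, p_empirical = object$p_empirical,
             seed = object$seed)
}

#' @export
plot.psa_result <- function(x, breaks = 50, ...) {
  graphics::hist(x$le_lob - x$le_sabr, breaks = breaks,
                 xlab = "LE difference, lobectomy - SABR (years)",
                 main = sprintf("PSA at age %g", x$age), ...)
  graphics::abline(v = 0, lty = 2)
  graphics::abline(v = x$mean_diff, col = 2, lwd = 2)
  invisible(x)
}

#' PSA iterations as a data frame
#'
#' One row per iteration: the two arms' life expectancies and their
#' difference, for export alongside the JSON summary.
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @export
as.data.frame.psa_result <- function(x, ...) {
  data.frame(iteration = seq_len(x$n_iter), le_lob = x$le_lob,
             le_sabr = x$le_sabr, diff = x$le_lob - x$le_sabr)
}
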