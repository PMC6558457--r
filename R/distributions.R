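#' Fit a sampling distribution to a probability estimate
#'
#' For the probabilistic sensitivity analysis each uncertain probability is
#' given a beta distribution whose mean equals the point estimate and whose
#' 2.5\%/97.5\% quantiles match the reported (low, high) range as closely as
#' possible. The beta shape is found by a one-dimensional numeric search over
#' the concentration `alpha + beta` with the mean held fixed. Degenerate
#' estimates, and point estimates of exactly 0 or 1, yield a point mass.
#' If no beta with the required mean can reproduce the range to within a
#' quarter of its width, the fit falls back to `Uniform(low, high)` with a
#' warning; the fallback is part of the contract, not an error.
#'
#' @param est A [prob_estimate()].
#' @return An object of class `psa_dist`: a list with `family`
#'   (`"beta"`, `"uniform"` or `"point"`) and the family's parameters.
#' @examples
#' fit_psa_distribution(prob_estimate(0.6268, 0.4624, 0.8105))
#' @export
fit_psa_distribution <- function(est) {
  validate_prob_estimate(est)
  m <- est$point
  if (is_degenerate(est) || m <= 0 || m >= 1)
    return(structure(list(family = "point", value = m, mean = m),
                     class = "psa_dist"))
  qfun <- function(conc) {
    a <- m * conc
    b <- (1 - m) * conc
    c(stats::qbeta(0.025, a, b), stats::qbeta(0.975, a, b))
  }
  obj <- function(log_conc) {
    q <- qfun(exp(log_conc))
    (q[1] - est$low)^2 + (q[2] - est$high)^2
  }
  opt <- stats::optimize(obj, interval = log(c(1e-2, 1e9)))
  conc <- exp(opt$minimum)
  q <- qfun(conc)
  width <- est$high - est$low
  if (max(abs(q - c(est$low, est$high))) > 0.25 * width + 1e-9) {
    warning(sprintf(
      "beta fit cannot reproduce range (%.4g-%.4g) at mean %.4g; falling back to Uniform",
      est$low, est$high, m), call. = FALSE)
    return(structure(list(family = "uniform", low = est$low, high = est$high,
                          mean = (est$low + est$high) / 2),
                     class = "psa_dist"))
  }
  structure(list(family = "beta", shape1 = m * conc, shape2 = (1 - m) * conc,
                 mean = m, q025 = q[1], q975 = q[2]),
            class = "psa_dist")
}

#' Draw from a fitted PSA distribution
#'
#' @param dist A `psa_dist` from [fit_psa_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of `n` values in `[0, 1]`. Uses the current RNG
#'   stream; seed management is the caller's responsibility.
#' @export
sample_psa_distribution <- function(dist, n) {
  stopifnot(inherits(dist, "psa_dist"))
  switch(dist$family,
    point   = rep(dist$value, n),
    uniform = stats::runif(n, dist$low, dist$high),
    beta    = stats::rbeta(n, dist$shape1, dist$shape2)
  )
}

#' @export
print.psa_dist <- function(x, ...) {
  switch(x$family,
    point = cat(sprintf("PSA distribution: point mass at %.4f\n", x$value)),
    uniform = cat(sprintf("PSA distribution: Uniform(%.4f, %.4f)\n",
                          x$low, x$high)),
    beta = cat(sprintf(
      "PSA distribution: Beta(%.3f, %.3f), mean %.4f, 95%% CI %.4f-%.4f\n",
      x$shape1, x$shape2, x$mean, x$q025, x$q975))
  )
  invisible(x)
}
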