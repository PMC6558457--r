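#' Predicted overall survival versus age at diagnosis
#'
#' Runs one deterministic cohort per age and reads survival at a fixed
#' horizon, producing the model's survival-versus-age validation curve
#' (5-year survival for lobectomy, 3-year for SABR are the horizons most
#' often reported by the respective literatures).
#'
#' @param arm `"lobectomy"` or `"sabr"`.
#' @param horizon Survival read-out time in years.
#' @param ages Ages at diagnosis, within `[45, 85]`.
#' @param params A `lung_params` object.
#' @return Object of class `os_curve`: data frame with columns `age`,
#'   `predicted_os`, plus `arm`/`horizon` attributes.
#' @examples
#' \donttest{
#' predicted_os_curve("lobectomy", 5, ages = seq(45, 85, 10))
#' }
#' @export
predicted_os_curve <- function(arm = c("lobectomy", "sabr"), horizon = 5,
                               ages = 45:85, params = default_params()) {
  arm <- match.arg(arm)
  os <- vapply(ages, function(a)
    survival_at(run_cohort(arm, a, params), horizon), 0)
  out <- data.frame(age = ages, predicted_os = os)
  attr(out, "arm") <- arm
  attr(out, "horizon") <- horizon
  class(out) <- c("os_curve", "data.frame")
  out
}

#' @export
plot.os_curve <- function(x, ...) {
  graphics::plot(x$age, x$predicted_os, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "Age at diagnosis (years)",
                 ylab = sprintf("%g-year overall survival",
                                attr(x, "horizon")),
                 main = sprintf("Predicted %s survival vs age",
                                attr(x, "arm")), ...)
  invisible(x)
}

#' Read a literature study-point table
#'
#' Delimited table with header `label,median_age,horizon,observed_os` and
#' an optional `n_patients` column used for size-weighted averaging.
#'
#' @param path File path.
#' @return Data frame of study points.
#' @export
read_study_points <- function(path) {
  df <- utils::read.csv(path)
  req <- c("label", "median_age", "horizon", "observed_os")
  if (!all(req %in% names(df)))
    stop("study-point table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  df
}

#' Compare predicted survival with literature outcomes
#'
#' Overlays literature survival points on the model's
#' survival-versus-age curve: each study's observed survival is compared
#' with the model prediction at the study's median age (linear
#' interpolation in age between curve nodes), and the deviations
#' (observed minus predicted) are averaged, by default weighting each
#' study by its number of patients when an `n_patients` column is present.
#'
#' @param curve An [predicted_os_curve()] result.
#' @param points Data frame of study points (see [read_study_points()]).
#' @param weighted Weight the mean deviation by `n_patients` when
#'   available (default `TRUE`); the unweighted mean is always reported
#'   alongside.
#' @return Object of class `validation_summary`: list with `points` (the
#'   input plus `predicted_os` and `deviation` columns), `mean_deviation`,
#'   `mean_deviation_unweighted`, `weighted`.
#' @export
compare_to_studies <- function(curve, points, weighted = TRUE) {
  stopifnot(inherits(curve, "os_curve"))
  if (is.character(points)) points <- read_study_points(points)
  if (!is.data.frame(points) || nrow(points) == 0)
    stop("'points' must be a non-empty study-point table", call. = FALSE)
  if (any(points$median_age < min(curve$age) |
          points$median_age > max(curve$age)))
    stop("every study's median age must lie inside the curve's age range",
         call. = FALSE)
  if ("horizon" %in% names(points) &&
      any(points$horizon != attr(curve, "horizon")))
    warning("study horizons differ from the curve's horizon", call. = FALSE)
  pred <- stats::approx(curve$age, curve$predicted_os,
                        xout = points$median_age)$y
  points$predicted_os <- pred
  points$deviation <- points$observed_os - pred
  w <- if (weighted && "n_patients" %in% names(points))
    points$n_patients else rep(1, nrow(points))
  structure(list(
    points = points,
    mean_deviation = sum(points$deviation * w) / sum(w),
    mean_deviation_unweighted = mean(points$deviation),
    weighted = weighted && "n_patients" %in% names(points),
    arm = attr(curve, "arm"), horizon = attr(curve, "horizon")
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf(
    "model validation (%s arm, %g-year survival, %d studies):\n",
    x$arm, x$horizon, nrow(x$points)))
  cat(sprintf("  mean deviation observed - predicted: %+.3f%s\n",
              x$mean_deviation,
              if (x$weighted) " (weighted by study size)" else ""))
  cat(sprintf("  unweighted mean deviation: %+.3f\n",
              x$mean_deviation_unweighted))
  invisible(x)
}
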