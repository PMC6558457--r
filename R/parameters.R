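#' Probability estimate with an uncertainty range
#'
#' A point estimate of a probability together with the low/high ends of its
#' plausible range (as reported across the source studies). Degenerate
#' estimates (`low == point == high`) are allowed and denote parameters with
#' no usable uncertainty information.
#'
#' @param point Point estimate, in `[0, 1]`.
#' @param low Lower end of the plausible range. Defaults to `point`.
#' @param high Upper end of the plausible range. Defaults to `point`.
#' @return An object of class `prob_estimate` with fields `point`, `low`,
#'   `high`.
#' @examples
#' prob_estimate(0.6268, 0.4624, 0.8105)
#' @export
prob_estimate <- function(point, low = point, high = point) {
  x <- structure(list(point = point, low = low, high = high),
                 class = "prob_estimate")
  validate_prob_estimate(x, deparse(substitute(point)))
  x
}

validate_prob_estimate <- function(x, name = "estimate") {
  for (f in c("point", "low", "high")) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("'%s$%s' must be a single number", name, f), call. = FALSE)
  }
  if (x$low < 0 || x$high > 1 || x$low > x$point || x$point > x$high)
    stop(sprintf(
      "'%s' violates 0 <= low <= point <= high <= 1 (point=%g, low=%g, high=%g)",
      name, x$point, x$low, x$high), call. = FALSE)
  invisible(x)
}

is_degenerate <- function(est) est$low == est$high

#' @export
print.prob_estimate <- function(x, ...) {
  if (is_degenerate(x)) {
    cat(sprintf("probability estimate: %.4f (fixed)\n", x$point))
  } else {
    cat(sprintf("probability estimate: %.4f (%.4f-%.4f)\n",
                x$point, x$low, x$high))
  }
  invisible(x)
}

#' Age-indexed annual probability curve
#'
#' Represents an annual probability (e.g. all-cause mortality) as a function
#' of age, anchored at a set of (age, value) pairs. Between anchors the curve
#' is interpolated on the chosen scale; beyond the outermost anchors it is
#' extrapolated on the same scale and the result is clamped to `[0, 1]`.
#' The default log-linear scale makes the curve exponential in age between
#' anchors (Gompertz-like), which is how both all-cause and operative
#' mortality behave over the 45-85 age span.
#'
#' @param ages Strictly increasing anchor ages (years).
#' @param values Annual probabilities at the anchors, each in `[0, 1]`.
#' @param kind Interpolation scale: `"loglinear"` (default), `"linear"` or
#'   `"step"` (left-continuous step function).
#' @return An object of class `age_curve`.
#' @seealso [eval_age_curve()]
#' @examples
#' bg <- age_curve(c(45, 85), c(0.002491, 0.082156))
#' eval_age_curve(bg, 65)
#' @export
age_curve <- function(ages, values, kind = c("loglinear", "linear", "step")) {
  kind <- match.arg(kind)
  if (length(ages) != length(values) || length(ages) < 1L)
    stop("'ages' and 'values' must be non-empty and of equal length",
         call. = FALSE)
  if (is.unsorted(ages, strictly = TRUE))
    stop("anchor ages must be strictly increasing", call. = FALSE)
  if (any(values < 0 | values > 1))
    stop("anchor values must lie in [0, 1]", call. = FALSE)
  if (kind == "loglinear" && any(values <= 0))
    stop("log-linear interpolation needs strictly positive anchor values",
         call. = FALSE)
  structure(list(ages = as.numeric(ages), values = as.numeric(values),
                 kind = kind),
            class = "age_curve")
}

#' Evaluate an age curve
#'
#' Returns the annual probability at the given age(s). Anchor ages reproduce
#' their anchor values exactly; other ages are interpolated or extrapolated on
#' the curve's scale, and the result is clamped to `[0, 1]`.
#'
#' @param curve An [age_curve()].
#' @param age Age(s) in years, each `>= 0`.
#' @return Numeric vector of annual probabilities in `[0, 1]`.
#' @export
eval_age_curve <- function(curve, age) {
  stopifnot(inherits(curve, "age_curve"))
  if (any(!is.finite(age)) || any(age < 0))
    stop("'age' must be finite and non-negative", call. = FALSE)
  a <- curve$ages
  if (length(a) == 1L) return(rep(curve$values, length(age)))
  v <- switch(curve$kind,
    step = curve$values[pmax(1L, findInterval(age, a))],
    linear = interp_extrap(age, a, curve$values),
    loglinear = exp(interp_extrap(age, a, log(curve$values)))
  )
  hit <- match(age, a)  # anchors reproduce their values exactly
  v[!is.na(hit)] <- curve$values[hit[!is.na(hit)]]
  pmin(pmax(v, 0), 1)
}

# piecewise-linear interpolation with end-segment slope extrapolation
interp_extrap <- function(x, xs, ys) {
  n <- length(xs)
  i <- findInterval(x, xs, all.inside = TRUE)
  ys[i] + (ys[i + 1L] - ys[i]) * (x - xs[i]) / (xs[i + 1L] - xs[i])
}

#' @export
print.age_curve <- function(x, ...) {
  cat(sprintf("age curve (%s), %d anchors:\n", x$kind, length(x$ages)))
  print(stats::setNames(x$values, x$ages))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parameter set

# parameter fields that are probability estimates, in a fixed order
# (the order also fixes the PSA draw order, part of the seeding contract)
.estimate_fields <- c(
  "mort_sabr", "mort_conv_rt", "mort_progression",
  "p_prog_lob", "p_prog_sabr",
  "frac_lr_lob", "frac_lr_sabr", "frac_rr_lob", "frac_rr_sabr",
  "p_salv_lr_sabr", "p_salv_rr_lob", "p_salv_rr_sabr", "p_salv_dm",
  "p_prog_post_salv_lr_sabr", "p_prog_post_salv_rr_lob",
  "p_prog_post_salv_rr_sabr", "p_pn_positive"
)
.curve_fields <- c("bg_mortality", "mort_lobectomy")
.scalar_fields <- c("n_cycles", "cycle_length")
.param_fields <- c(.curve_fields, .estimate_fields, .scalar_fields)

#' Five-year age-band mortality schedule
#'
#' Builds an abridged-life-table style [age_curve()]: a step function over
#' five-year age bands (45-49, 50-54, ..., 85-89, and optionally beyond)
#' whose band rates run from `low` (the 45-49 band) to `high` (the 85-89
#' band) on a log-quadratic schedule,
#' `log q(x) = log(low) + b (x - 45) + curvature (x - 45)^2`,
#' with `b` chosen so that the 85 band equals `high`. `curvature = 0` gives
#' a geometric (Gompertz, log-linear across bands) progression; a small
#' positive curvature reproduces the mild log-convexity of contemporary
#' national life tables, whose mid-adult death rates fall below a two-point
#' Gompertz fit through the same endpoints. Beyond age 85 the band rates
#' continue geometrically at the average per-band ratio, capped at 1.
#'
#' @param low Annual rate of the 45-49 band.
#' @param high Annual rate of the 85-89 band.
#' @param curvature Log-quadratic coefficient, per year squared.
#' @param extend_to Last band start age (bands every 5 years up to this age).
#' @return An [age_curve()] of kind `"step"`.
#' @examples
#' mortality_bands(0.002491, 0.082156, curvature = 7e-4)
#' @export
mortality_bands <- function(low, high, curvature = 0, extend_to = 100) {
  stopifnot(low > 0, high > 0, extend_to >= 85)
  b <- (log(high) - log(low) - curvature * 40^2) / 40
  ages <- seq(45, 85, 5)
  vals <- exp(log(low) + b * (ages - 45) + curvature * (ages - 45)^2)
  if (extend_to > 85) {
    ext <- seq(90, extend_to, 5)
    r <- (high / low)^(1 / 8)
    vals <- c(vals, high * r^seq_along(ext))
    ages <- c(ages, ext)
  }
  age_curve(ages, pmin(vals, 1), kind = "step")
}

#' Packaged base-case parameter set
#'
#' Returns the base-case model inputs. Mortality-by-age inputs are
#' five-year age-band schedules (see [mortality_bands()]): annual all-cause
#' mortality of the general population runs from 0.002491 (45-49 band) to
#' 0.082156 (85-89 band) with the mild log-convexity of a national life
#' table (curvature `7e-4`), continued beyond 85; 90-day post-lobectomy
#' mortality runs geometrically from 0.0133 to 0.0800 over the same bands.
#' Point(range) estimates: SABR procedure mortality 0.0037 (0-0.0208),
#' age-invariant; one-year progression probabilities 0.0400 (lobectomy) and
#' 0.0790 (SABR); recurrence-site splits, salvage probabilities and
#' post-salvage progression probabilities per arm; and annual mortality of
#' progressive disease under chemotherapy plus best supportive care, 0.6268
#' (0.4624-0.8105). All values are pooled estimates from a published
#' systematic review of lobectomy and SABR outcomes in node-negative NSCLC
#' under 3 cm.
#'
#' @return A validated object of class `lung_params`.
#' @examples
#' p <- default_params()
#' p$p_prog_lob
#' @export
default_params <- function() {
  p <- list(
    bg_mortality  = mortality_bands(0.002491, 0.082156, curvature = 7e-4),
    mort_lobectomy = mortality_bands(0.0133, 0.0800, extend_to = 85),
    mort_sabr     = prob_estimate(0.0037, 0, 0.0208),
    mort_conv_rt  = prob_estimate(0.0010),
    mort_progression = prob_estimate(0.6268, 0.4624, 0.8105),
    p_prog_lob    = prob_estimate(0.0400, 0.0133, 0.0742),
    p_prog_sabr   = prob_estimate(0.0790, 0.0490, 0.1284),
    frac_lr_lob   = prob_estimate(0),
    frac_lr_sabr  = prob_estimate(0.1844, 0.1451, 0.4285),
    frac_rr_lob   = prob_estimate(0.2784, 0.0952, 0.4000),
    frac_rr_sabr  = prob_estimate(0.1781, 0, 0.3333),
    p_salv_lr_sabr = prob_estimate(0.2622, 0.2171, 0.4865),
    p_salv_rr_lob  = prob_estimate(0.3446, 0.3172, 0.3888),
    p_salv_rr_sabr = prob_estimate(0.3010, 0.2941, 0.3095),
    p_salv_dm      = prob_estimate(0),
    p_prog_post_salv_lr_sabr = prob_estimate(0.0679, 0, 0.0799),
    p_prog_post_salv_rr_lob  = prob_estimate(0.2639, 0.2342, 0.2865),
    p_prog_post_salv_rr_sabr = prob_estimate(0.3115, 0.2540, 0.3835),
    p_pn_positive = prob_estimate(0),
    n_cycles      = 15L,
    cycle_length  = 1
  )
  validate_params(structure(p, class = "lung_params"))
}

#' Validate a parameter set
#'
#' Checks every field of a `lung_params` object: probability-estimate
#' invariants, age-curve invariants, `n_cycles >= 1`, and the per-arm
#' constraint that the local-only and regional recurrence fractions sum to at
#' most 1 (the distant fraction is the complement).
#'
#' @param params A `lung_params` object.
#' @return The validated object, invisibly usable in a pipe.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "lung_params"))
    stop("'params' must be a 'lung_params' object", call. = FALSE)
  missing <- setdiff(.param_fields, names(params))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(params), .param_fields)
  if (length(extra))
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (f in .estimate_fields) {
    if (!inherits(params[[f]], "prob_estimate"))
      stop(sprintf("'%s' must be a prob_estimate", f), call. = FALSE)
    validate_prob_estimate(params[[f]], f)
  }
  for (f in .curve_fields)
    if (!inherits(params[[f]], "age_curve"))
      stop(sprintf("'%s' must be an age_curve", f), call. = FALSE)
  if (!is.numeric(params$n_cycles) || params$n_cycles < 1)
    stop("'n_cycles' must be >= 1", call. = FALSE)
  if (!identical(as.numeric(params$cycle_length), 1))
    stop("'cycle_length' is fixed at 1 year", call. = FALSE)
  for (arm in c("lob", "sabr")) {
    s <- params[[paste0("frac_lr_", arm)]]$point +
         params[[paste0("frac_rr_", arm)]]$point
    if (s > 1 + 1e-12)
      stop(sprintf(
        "recurrence-site fractions for arm '%s' sum to %g > 1", arm, s),
        call. = FALSE)
  }
  params
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named probability-estimate fields
#' replaced. A bare number replaces the point estimate and collapses the
#' range onto it; a [prob_estimate()] replaces the whole field.
#'
#' @param params A `lung_params` object.
#' @param ... Named replacements, e.g. `p_prog_lob = 0.054`.
#' @return A validated `lung_params` object.
#' @examples
#' p <- set_params(default_params(), p_prog_lob = 0.054)
#' @export
set_params <- function(params, ...) {
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == "")))
    stop("all replacements must be named", call. = FALSE)
  for (nm in names(dots)) {
    if (!nm %in% .param_fields)
      stop(sprintf("unknown parameter field '%s'", nm), call. = FALSE)
    v <- dots[[nm]]
    if (nm %in% .estimate_fields && is.numeric(v) && length(v) == 1L)
      v <- prob_estimate(v)
    params[[nm]] <- v
  }
  validate_params(params)
}

#' @export
print.lung_params <- function(x, ...) {
  cat("Markov model parameter set (lobectomy vs SABR, stage IA NSCLC)\n")
  cat(sprintf("  horizon: %d one-year cycles\n", as.integer(x$n_cycles)))
  for (f in .curve_fields)
    cat(sprintf("  %-26s anchors %s -> %s\n", f,
                paste(x[[f]]$ages, collapse = "/"),
                paste(format(x[[f]]$values, digits = 5), collapse = "/")))
  for (f in .estimate_fields) {
    e <- x[[f]]
    cat(sprintf("  %-26s %.4f%s\n", f, e$point,
                if (is_degenerate(e)) "" else
                  sprintf(" (%.4f-%.4f)", e$low, e$high)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Config I/O (YAML)

est_to_list <- function(e) list(point = e$point, low = e$low, high = e$high)
curve_to_list <- function(cv) list(ages = cv$ages, values = cv$values,
                                   kind = cv$kind)

#' Load a parameter set from a YAML configuration file
#'
#' Reads a model configuration and merges it over the packaged base case:
#' every field that is absent falls back to [default_params()], so an empty
#' (or `NULL`) config yields the base case. Unknown keys are rejected.
#' Probability estimates may be written either as a bare number (degenerate
#' range) or as a mapping with `point`, `low`, `high`; age curves as mappings
#' with `ages`, `values` and optional `kind`.
#'
#' @param path Path to a YAML file, or `NULL` for the packaged defaults.
#' @return A validated `lung_params` object.
#' @seealso [save_parameters()]
#' @export
load_parameters <- function(path = NULL) {
  base <- default_params()
  if (is.null(path)) return(base)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed config '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (is.null(cfg)) return(base)
  if (!is.list(cfg) || (length(cfg) && is.null(names(cfg))))
    stop("config must be a mapping of parameter names to values",
         call. = FALSE)
  unknown <- setdiff(names(cfg), .param_fields)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    base[[nm]] <-
      if (nm %in% .scalar_fields) {
        if (nm == "n_cycles") as.integer(v) else as.numeric(v)
      } else if (nm %in% .curve_fields) {
        age_curve(v$ages, v$values,
                  kind = if (is.null(v$kind)) "loglinear" else v$kind)
      } else if (is.numeric(v) && length(v) == 1L) {
        prob_estimate(v)
      } else {
        structure(list(point = v$point,
                       low = if (is.null(v$low)) v$point else v$low,
                       high = if (is.null(v$high)) v$point else v$high),
                  class = "prob_estimate")
      }
  }
  validate_params(base)
}

#' Save a parameter set to a YAML configuration file
#'
#' Writes every field, so `load_parameters(save_parameters(p, f))` is the
#' identity on `p`.
#'
#' @param params A `lung_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  validate_params(params)
  out <- list()
  for (f in .curve_fields) out[[f]] <- curve_to_list(params[[f]])
  for (f in .estimate_fields) out[[f]] <- est_to_list(params[[f]])
  out$n_cycles <- as.integer(params$n_cycles)
  out$cycle_length <- as.numeric(params$cycle_length)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Override background mortality with a life table
#'
#' Replaces the background-mortality curve with anchors taken from a
#' user-supplied life table (columns `age`, `annual_mortality`), e.g. a
#' national abridged life table. Rows must cover the modelled age span;
#' evaluation outside the table extrapolates on the chosen scale.
#'
#' @param params A `lung_params` object.
#' @param life_table Data frame with columns `age` and `annual_mortality`,
#'   or a path to a delimited file with that header.
#' @param kind Interpolation scale passed to [age_curve()].
#' @return The modified, validated `lung_params` object.
#' @export
set_life_table <- function(params, life_table, kind = "loglinear") {
  if (is.character(life_table))
    life_table <- utils::read.csv(life_table)
  req <- c("age", "annual_mortality")
  if (!all(req %in% names(life_table)))
    stop("life table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  o <- order(life_table$age)
  params$bg_mortality <- age_curve(life_table$age[o],
                                   life_table$annual_mortality[o],
                                   kind = kind)
  validate_params(params)
}
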