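#' Specification for synthetic fixtures
#'
#' Controls the synthetic-data generator that every test and example can
#' use in place of downloaded inputs: perturbed parameter tables with the
#' base case's structure, synthetic life tables, and synthetic literature
#' study-point tables.
#'
#' @param seed Integer seed; all fixtures are bit-reproducible from
#'   `(seed, spec)`.
#' @param jitter Fraction of each reported range used when perturbing the
#'   point estimates, in `[0, 1]`; 0 reproduces the base case exactly.
#' @param n_study_points Number of synthetic literature studies.
#' @param noise_sd Gaussian noise added to synthetic observed survival, in
#'   overall-survival probability units.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, jitter = 0.5, n_study_points = 11,
                         noise_sd = 0.02) {
  if (jitter < 0 || jitter > 1) stop("'jitter' must be in [0, 1]",
                                     call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (n_study_points < 1) stop("'n_study_points' must be >= 1",
                               call. = FALSE)
  structure(list(seed = as.integer(seed), jitter = jitter,
                 n_study_points = as.integer(n_study_points),
                 noise_sd = noise_sd),
            class = "fixture_spec")
}

#' Synthetic parameter table
#'
#' Draws a perturbed parameter set with the base case's structure: every
#' nondegenerate point estimate is drawn uniformly inside its reported
#' range, shrunk towards the point by `1 - jitter`
#' (`jitter = 0` reproduces the base case; `jitter = 1` uses the full
#' range). Ranges are kept, so all parameter-set invariants hold by
#' construction; `p_salv_dm` stays 0 (distant failures have no salvage
#' pathway).
#'
#' @param spec A [fixture_spec()].
#' @param base Parameter set to perturb.
#' @return A validated `lung_params`.
#' @examples
#' make_parameter_table(fixture_spec(seed = 7, jitter = 1))
#' @export
make_parameter_table <- function(spec = fixture_spec(),
                                 base = default_params()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    for (f in setdiff(.estimate_fields, "p_salv_dm")) {
      e <- base[[f]]
      if (is_degenerate(e)) next
      lo <- e$point - spec$jitter * (e$point - e$low)
      hi <- e$point + spec$jitter * (e$high - e$point)
      base[[f]]$point <- stats::runif(1, lo, hi)
    }
    validate_params(base)
  })
}

#' Synthetic life table
#'
#' Background-mortality override table (`age`, `annual_mortality`) built
#' from the base curve with multiplicative jitter of up to 10% per band,
#' for exercising [set_life_table()].
#'
#' @param spec A [fixture_spec()].
#' @param ages Ages at which to tabulate.
#' @param base Parameter set providing the underlying curve.
#' @return Data frame with columns `age`, `annual_mortality`.
#' @export
make_life_table <- function(spec = fixture_spec(), ages = seq(45, 100, 5),
                            base = default_params()) {
  stopifnot(inherits(spec, "fixture_spec"))
  v <- eval_age_curve(base$bg_mortality, ages)
  with_seed(spec$seed + 1L, {
    fac <- stats::runif(length(ages), 1 - 0.1 * spec$jitter,
                        1 + 0.1 * spec$jitter)
    data.frame(age = ages, annual_mortality = pmin(v * fac, 1))
  })
}

#' Synthetic literature study points
#'
#' Emulates the validation overlay's input: studies at uniform median ages
#' in `[45, 85]` whose observed survival is the model's own prediction plus
#' Gaussian noise of SD `noise_sd`, clipped to `[0, 1]`, with random study
#' sizes for the size-weighted average.
#'
#' @param arm `"lobectomy"` or `"sabr"`.
#' @param spec A [fixture_spec()].
#' @param params Parameter set used to predict survival.
#' @param horizon Survival read-out in years (5 for lobectomy-like studies,
#'   3 for SABR-like studies).
#' @return Data frame with columns `label`, `median_age`, `horizon`,
#'   `observed_os`, `n_patients`.
#' @export
make_study_points <- function(arm = c("lobectomy", "sabr"),
                              spec = fixture_spec(),
                              params = default_params(),
                              horizon = if (match.arg(arm) == "lobectomy")
                                5 else 3) {
  arm <- match.arg(arm)
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_study_points
  with_seed(spec$seed + 2L, {
    ages <- stats::runif(n, 45, 85)
    pred <- vapply(ages, function(a)
      survival_at(run_cohort(arm, a, params), horizon), 0)
    obs <- pmin(pmax(pred + stats::rnorm(n, 0, spec$noise_sd), 0), 1)
    data.frame(label = sprintf("synthetic-study-%02d", seq_len(n)),
               median_age = ages, horizon = horizon, observed_os = obs,
               n_patients = sample(30:500, n, replace = TRUE))
  })
}

#' Write a full synthetic fixture set to a directory
#'
#' Writes a perturbed parameter config (`params.yaml`), a synthetic life
#' table (`life_table.csv`) and one study-point table per arm.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [fixture_spec()].
#' @return Character vector of the files written, invisibly.
#' @export
write_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- make_parameter_table(spec)
  files <- file.path(dir, c("params.yaml", "life_table.csv",
                            "study_points_lobectomy.csv",
                            "study_points_sabr.csv"))
  save_parameters(params, files[1])
  utils::write.csv(make_life_table(spec), files[2], row.names = FALSE)
  utils::write.csv(make_study_points("lobectomy", spec, params), files[3],
                   row.names = FALSE)
  utils::write.csv(make_study_points("sabr", spec, params), files[4],
                   row.names = FALSE)
  invisible(files)
}
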