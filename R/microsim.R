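# run code with a private, restored RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is required", call. = FALSE)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

#' First-order microsimulation of individual patients
#'
#' Simulates `n_patients` independent realizations of the Markov chain, each
#' walking through the same age-dependent transition rows as the
#' deterministic cohort of [run_cohort()]. A patient dying in cycle `t` is
#' credited `t - 0.5` life years (transitions happen halfway through the
#' cycle); patients alive at the horizon are credited the full horizon. The
#' sample mean of the life years is an unbiased estimate of the cohort life
#' expectancy and converges to it as `n_patients` grows.
#'
#' @param arm `"lobectomy"` or `"sabr"`.
#' @param start_age Age at diagnosis, in `[45, 85]`.
#' @param params A `lung_params` object.
#' @param n_patients Number of virtual patients (default 10000, the size of
#'   each arm of the virtual trial).
#' @param seed Integer seed; required, and recorded in the result. The
#'   global RNG state is left untouched.
#' @return An object of class `microsim_result`: list with `arm`,
#'   `n_patients`, `life_years` (one value per patient), `final_state`,
#'   `seed`.
#' @examples
#' ms <- microsimulate("sabr", 75, default_params(), n_patients = 500, seed = 1)
#' mean(ms$life_years)
#' @export
microsimulate <- function(arm = c("lobectomy", "sabr"), start_age,
                          params = default_params(), n_patients = 10000,
                          seed) {
  arm <- match.arg(arm)
  validate_params(params)
  .check_salvage_dm(params)
  if (n_patients < 1) stop("'n_patients' must be >= 1", call. = FALSE)
  states <- health_states(arm)
  ns <- nrow(states)
  i_death <- which(states$name == "death")
  n <- as.integer(params$n_cycles) + 1L
  ages <- start_age + seq_len(n) - 1
  bg <- eval_age_curve(params$bg_mortality, ages)
  ml <- eval_age_curve(params$mort_lobectomy, ages)
  pts <- .param_points(params)
  life <- rep(NA_real_, n_patients)
  cur <- rep(1L, n_patients)  # everyone starts in `initial`
  with_seed(seed, {
    for (t in seq_len(n)) {
      M <- .trans_matrix(arm, pts, bg[t], ml[t])
      prev <- cur  # transitions act on the cycle-start states
      alive_states <- setdiff(unique(prev), i_death)
      for (s in alive_states) {
        idx <- which(prev == s)
        nxt <- sample.int(ns, length(idx), replace = TRUE, prob = M[s, ])
        cur[idx] <- nxt
        died <- idx[nxt == i_death]
        life[died] <- t - 0.5
      }
    }
  })
  life[is.na(life)] <- n
  structure(list(arm = arm, start_age = start_age, n_patients = n_patients,
                 life_years = life, final_state = states$name[cur],
                 horizon = n, seed = as.integer(seed)),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf(
    "microsimulation: %s arm, age %g, %d patients (seed %d)\n",
    x$arm, x$start_age, x$n_patients, x$seed))
  cat(sprintf("  mean life years %.3f (SE %.3f), %0.1f%% alive at %d years\n",
              mean(x$life_years),
              stats::sd(x$life_years) / sqrt(x$n_patients),
              100 * mean(x$life_years == x$horizon), x$horizon))
  invisible(x)
}
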