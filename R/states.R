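#' Health states of the two-arm model
#'
#' Enumerates the Markov health states of one arm. The lobectomy arm has 9
#' states and the SABR arm 13 (22 distinct states in total). Three kinds of
#' state occur:
#' \itemize{
#'   \item persistent states (`tunnel = FALSE`, `transient = FALSE`): the
#'     disease-free (NED) states, disease progression, and death, which can
#'     be occupied for more than one cycle;
#'   \item tunnel states (`tunnel = TRUE`, `transient = FALSE`): occupied for
#'     exactly one cycle (the initial/perioperative state, adjuvant therapy
#'     after node-positive lobectomy);
#'   \item event states (`transient = TRUE`): recurrence detection, salvage
#'     procedures and terminal bridges, which resolve within a cycle ("a very
#'     short time interval") and therefore never hold cohort occupancy at a
#'     cycle boundary.
#' }
#'
#' @param arm `"lobectomy"` or `"sabr"`.
#' @return A data frame with columns `name`, `arm`, `absorbing`, `tunnel`,
#'   `transient`, one row per state, in the model's canonical order.
#' @examples
#' nrow(health_states("lobectomy"))  # 9
#' nrow(health_states("sabr"))       # 13
#' @export
health_states <- function(arm = c("lobectomy", "sabr")) {
  arm <- match.arg(arm)
  if (arm == "lobectomy") {
    df <- data.frame(
      name = c("initial", "ned", "pn_adjuvant", "rr_detected",
               "salvage_rt_rr", "ned_post_salvage_rr", "progression",
               "bsc_bridge", "death"),
      absorbing = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE),
      tunnel    = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                    FALSE),
      transient = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE,
                    FALSE)
    )
  } else {
    df <- data.frame(
      name = c("initial", "ned", "lr_detected", "rr_detected", "dm_detected",
               "salvage_lobectomy_lr", "salvage_rt_rr",
               "ned_post_salvage_lr", "ned_post_salvage_rr", "progression",
               "untreated_bridge", "bsc_bridge", "death"),
      absorbing = c(rep(FALSE, 12), TRUE),
      tunnel    = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                    FALSE, TRUE, TRUE, FALSE),
      transient = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                    FALSE, FALSE, TRUE, TRUE, FALSE)
    )
  }
  df$arm <- arm
  df
}

# plain-list point estimates + curve handles, for fast matrix construction
.param_points <- function(params) {
  pts <- lapply(params[.estimate_fields], `[[`, "point")
  names(pts) <- .estimate_fields
  pts
}

# Transition matrix for one arm at one attained age, from point values.
# bg: background annual mortality at the attained age; ml: 90-day lobectomy
# mortality at the attained age (primary resection in cycle 1, salvage
# lobectomy for local recurrence in the SABR arm thereafter).
.trans_matrix <- function(arm, pts, bg, ml) {
  mrt <- pts$mort_conv_rt
  if (arm == "lobectomy") {
    M <- matrix(0, 9L, 9L)
    surv <- (1 - ml) * (1 - bg)
    M[1L, 9L] <- 1 - surv
    M[1L, 3L] <- surv * pts$p_pn_positive
    M[1L, 2L] <- surv * (1 - pts$p_pn_positive)
    d <- 1 - (1 - bg) * (1 - mrt)
    M[3L, 9L] <- d
    M[3L, 2L] <- 1 - d
    p <- pts$p_prog_lob
    f_lr <- pts$frac_lr_lob
    f_rr <- pts$frac_rr_lob
    f_dm <- 1 - f_lr - f_rr
    ps_rr <- pts$p_salv_rr_lob
    ev <- (1 - bg) * p
    M[2L, 2L] <- (1 - bg) * (1 - p)
    M[2L, 6L] <- ev * f_rr * ps_rr * (1 - mrt)
    M[2L, 7L] <- ev * (f_lr + f_rr * (1 - ps_rr) + f_dm)
    M[2L, 9L] <- bg + ev * f_rr * ps_rr * mrt
    M[4L, 6L] <- ps_rr * (1 - mrt)
    M[4L, 9L] <- ps_rr * mrt
    M[4L, 7L] <- 1 - ps_rr
    M[5L, 6L] <- 1 - mrt
    M[5L, 9L] <- mrt
    p2 <- pts$p_prog_post_salv_rr_lob
    M[6L, 6L] <- (1 - bg) * (1 - p2)
    M[6L, 7L] <- (1 - bg) * p2
    M[6L, 9L] <- bg
    d <- 1 - (1 - bg) * (1 - pts$mort_progression)
    M[7L, 9L] <- d
    M[7L, 7L] <- 1 - d
    M[8L, 9L] <- 1
    M[9L, 9L] <- 1
  } else {
    M <- matrix(0, 13L, 13L)
    surv <- (1 - pts$mort_sabr) * (1 - bg)
    M[1L, 13L] <- 1 - surv
    M[1L, 2L] <- surv
    p <- pts$p_prog_sabr
    f_lr <- pts$frac_lr_sabr
    f_rr <- pts$frac_rr_sabr
    f_dm <- 1 - f_lr - f_rr
    ps_lr <- pts$p_salv_lr_sabr
    ps_rr <- pts$p_salv_rr_sabr
    ev <- (1 - bg) * p
    M[2L, 2L] <- (1 - bg) * (1 - p)
    M[2L, 8L] <- ev * f_lr * ps_lr * (1 - ml)
    M[2L, 9L] <- ev * f_rr * ps_rr * (1 - mrt)
    M[2L, 10L] <- ev * (f_lr * (1 - ps_lr) + f_rr * (1 - ps_rr) + f_dm)
    M[2L, 13L] <- bg + ev * (f_lr * ps_lr * ml + f_rr * ps_rr * mrt)
    M[3L, 8L] <- ps_lr * (1 - ml)
    M[3L, 13L] <- ps_lr * ml
    M[3L, 10L] <- 1 - ps_lr
    M[4L, 9L] <- ps_rr * (1 - mrt)
    M[4L, 13L] <- ps_rr * mrt
    M[4L, 10L] <- 1 - ps_rr
    M[5L, 10L] <- 1
    M[6L, 8L] <- 1 - ml
    M[6L, 13L] <- ml
    M[7L, 9L] <- 1 - mrt
    M[7L, 13L] <- mrt
    p2 <- pts$p_prog_post_salv_lr_sabr
    M[8L, 8L] <- (1 - bg) * (1 - p2)
    M[8L, 10L] <- (1 - bg) * p2
    M[8L, 13L] <- bg
    p2 <- pts$p_prog_post_salv_rr_sabr
    M[9L, 9L] <- (1 - bg) * (1 - p2)
    M[9L, 10L] <- (1 - bg) * p2
    M[9L, 13L] <- bg
    d <- 1 - (1 - bg) * (1 - pts$mort_progression)
    M[10L, 13L] <- d
    M[10L, 10L] <- 1 - d
    M[11L, 10L] <- 1
    M[12L, 13L] <- 1
    M[13L, 13L] <- 1
  }
  M
}

#' Transition matrix at an attained age
#'
#' Builds the full one-cycle transition matrix of one arm for a cohort whose
#' members have the given attained age during the cycle. Competing risks
#' within a cycle combine as independent events, with death taking precedence
#' over disease transitions; each row sums to 1 by construction. The
#' `initial` row describes the first post-treatment year (procedure-related
#' mortality combined with background mortality); it is only ever occupied in
#' cycle 1. Recurrence events resolve within the cycle: patients leaving NED
#' land directly in a post-salvage NED state, in disease progression
#' (unsalvaged locoregional failures and all distant failures), or in death
#' (background mortality or mortality of the salvage procedure). Event
#' states therefore carry topology (their rows give the within-event split)
#' but never hold occupancy.
#'
#' @param arm `"lobectomy"` or `"sabr"`.
#' @param age Attained age (years) during the cycle.
#' @param params A `lung_params` object.
#' @return A square matrix with state names on both dimensions.
#' @seealso [transition_row()], [health_states()]
#' @export
transition_matrix <- function(arm = c("lobectomy", "sabr"), age, params) {
  arm <- match.arg(arm)
  validate_params(params)
  if (!is.numeric(age) || length(age) != 1L || age < 0)
    stop("'age' must be a single non-negative number", call. = FALSE)
  .check_salvage_dm(params)
  M <- .trans_matrix(arm, .param_points(params),
                     eval_age_curve(params$bg_mortality, age),
                     eval_age_curve(params$mort_lobectomy, age))
  nm <- health_states(arm)$name
  dimnames(M) <- list(from = nm, to = nm)
  M
}

# distant failures have no salvage pathway in this topology
.check_salvage_dm <- function(params) {
  if (params$p_salv_dm$point != 0)
    stop("'p_salv_dm' must be 0: distant failures enter disease progression ",
         "without salvage in this model", call. = FALSE)
  invisible(TRUE)
}

#' Transition probabilities out of one state
#'
#' @param arm `"lobectomy"` or `"sabr"`.
#' @param state State name (see [health_states()]).
#' @param age Attained age (years) during the cycle.
#' @param params A `lung_params` object.
#' @return Named numeric vector over the arm's states, summing to 1.
#' @export
transition_row <- function(arm = c("lobectomy", "sabr"), state, age, params) {
  arm <- match.arg(arm)
  M <- transition_matrix(arm, age, params)
  if (!state %in% rownames(M))
    stop(sprintf("unknown state '%s' for arm '%s'", state, arm),
         call. = FALSE)
  M[state, ]
}
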