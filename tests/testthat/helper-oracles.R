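# Independent oracles used across the suite.

# Life expectancy by exhaustive enumeration of all state paths, weighted by
# path probability: walks every sequence of states through the per-cycle
# transition matrices, crediting t - 0.5 years for a death during cycle t
# and the full horizon for survivors. Exponential in the horizon; only for
# tiny n_cycles.
enum_le_oracle <- function(arm, start_age, params) {
  nf <- as.integer(params$n_cycles) + 1L
  Ms <- lapply(seq_len(nf), function(t)
    transition_matrix(arm, start_age + t - 1, params))
  ns <- nrow(Ms[[1]])
  i_death <- which(colnames(Ms[[1]]) == "death")
  rec <- function(b, s, pr) {
    if (b == nf) return(pr * nf)
    M <- Ms[[b + 1L]]
    out <- 0
    for (s2 in seq_len(ns)) {
      p2 <- pr * M[s, s2]
      if (p2 == 0) next
      out <- out + if (s2 == i_death) p2 * (b + 0.5) else rec(b + 1L, s2, p2)
    }
    out
  }
  rec(0L, 1L, 1)
}

# a parameter set whose two arms are effectively identical
symmetric_params <- function() {
  p <- default_params()
  p$mort_lobectomy <- age_curve(45, 0.0037)
  p <- set_params(p,
    mort_sabr = prob_estimate(0.0037),
    p_prog_sabr = prob_estimate(0.0400),
    frac_lr_sabr = prob_estimate(0),
    frac_rr_sabr = prob_estimate(0.2784),
    p_salv_rr_sabr = prob_estimate(0.3446),
    p_prog_post_salv_rr_sabr = prob_estimate(0.2639))
  p
}

# immortal cohort: no background, procedure or disease risk
immortal_params <- function() {
  p <- default_params()
  p$bg_mortality <- age_curve(45, 0, kind = "linear")
  p$mort_lobectomy <- p$bg_mortality
  for (f in c("mort_sabr", "mort_conv_rt", "mort_progression",
              "p_prog_lob", "p_prog_sabr",
              "p_prog_post_salv_lr_sabr", "p_prog_post_salv_rr_lob",
              "p_prog_post_salv_rr_sabr"))
    p[[f]] <- prob_estimate(0)
  validate_params(p)
}
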