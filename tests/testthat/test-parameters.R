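test_that("packaged defaults carry the reviewed point estimates", {
  p <- default_params()
  expect_s3_class(p, "lung_params")
  expect_identical(p$p_prog_lob$point, 0.0400)
  expect_identical(p$p_prog_sabr$point, 0.0790)
  expect_identical(p$mort_progression$point, 0.6268)
  expect_identical(p$frac_lr_lob$point, 0)
  expect_identical(as.integer(p$n_cycles), 15L)
  # mortality schedules anchor at the published endpoints
  expect_equal(eval_age_curve(p$bg_mortality, 45), 0.002491)
  expect_equal(eval_age_curve(p$bg_mortality, 85), 0.082156)
  expect_equal(eval_age_curve(p$mort_lobectomy, 45), 0.0133)
  expect_equal(eval_age_curve(p$mort_lobectomy, 85), 0.0800)
})

test_that("probability estimates and parameter sets are validated", {
  expect_error(prob_estimate(1.5), "0 <= low <= point <= high <= 1")
  expect_error(prob_estimate(0.5, 0.6, 0.7), "0 <= low")
  expect_error(prob_estimate(0.5, 0.4, 0.45), "0 <= low")
  expect_silent(prob_estimate(0.5, 0.5, 0.5))
  p <- default_params()
  p$mort_sabr <- structure(list(point = 1.5, low = 0, high = 2),
                           class = "prob_estimate")
  expect_error(validate_params(p), "mort_sabr")
  p <- default_params()
  p$extra_field <- 1
  expect_error(validate_params(p), "unknown parameter field")
  # recurrence-site fractions must leave room for the distant complement
  p <- default_params()
  p$frac_lr_sabr <- prob_estimate(0.7)
  p$frac_rr_sabr <- prob_estimate(0.6)
  expect_error(validate_params(p), "sum")
  expect_error(set_params(default_params(), p_prog_lob = 0.054), NA)
})

test_that("config round-trips and empty configs give the base case", {
  expect_identical(load_parameters(NULL), default_params())
  f <- withr::local_tempfile(fileext = ".yaml")
  save_parameters(default_params(), f)
  expect_equal(load_parameters(f), default_params())
  # modified set round-trips field by field
  p <- set_params(default_params(), p_prog_lob = prob_estimate(0.06, 0.02, 0.09))
  save_parameters(p, f)
  expect_equal(load_parameters(f), p)
  # packaged config file reproduces the defaults
  pkg <- system.file("extdata", "base_case.yaml", package = "sabrlob")
  expect_equal(load_parameters(pkg), default_params())
})

test_that("bad configs are rejected with named errors", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("mort_sabr:\n  point: 1.5\n  low: 0\n  high: 2", f)
  expect_error(load_parameters(f), "mort_sabr")
  writeLines("not_a_parameter: 0.5", f)
  expect_error(load_parameters(f), "unknown config key.*not_a_parameter")
  writeLines("p_prog_lob: [0.1, : 0.2", f)
  expect_error(load_parameters(f), "malformed config")
})

test_that("age curves interpolate, anchor exactly, and extrapolate capped", {
  bg <- age_curve(c(45, 85), c(0.002491, 0.082156), kind = "loglinear")
  expect_identical(eval_age_curve(bg, c(45, 85)), c(0.002491, 0.082156))
  # closed-form log-linear oracle at the midpoint
  expect_equal(eval_age_curve(bg, 65),
               exp((log(0.002491) + log(0.082156)) / 2))
  # extrapolation continues on the log scale, capped at 1
  slope <- (log(0.082156) - log(0.002491)) / 40
  expect_equal(eval_age_curve(bg, 95), 0.082156 * exp(10 * slope))
  expect_equal(eval_age_curve(bg, 200), 1)
  expect_error(eval_age_curve(bg, -1), "non-negative")
  lin <- age_curve(c(45, 85), c(0.1, 0.5), kind = "linear")
  expect_equal(eval_age_curve(lin, 65), 0.3)
  expect_equal(eval_age_curve(lin, 40), 0.05)
  stp <- age_curve(c(45, 50), c(0.1, 0.2), kind = "step")
  expect_equal(eval_age_curve(stp, c(45, 47, 50, 60)), c(0.1, 0.1, 0.2, 0.2))
  expect_error(age_curve(c(50, 45), c(0.1, 0.2)), "strictly increasing")
  expect_error(age_curve(c(45, 85), c(0, 0.5)), "positive")
})

test_that("packaged mortality schedules are monotone over ages 45-100", {
  p <- default_params()
  ages <- seq(45, 100, by = 0.5)
  for (f in c("bg_mortality", "mort_lobectomy")) {
    v <- eval_age_curve(p[[f]], ages)
    expect_true(all(diff(v) >= 0), label = paste(f, "monotone"))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("life-table overrides replace the background schedule", {
  lt <- data.frame(age = c(45, 65, 85),
                   annual_mortality = c(0.002, 0.01, 0.08))
  p <- set_life_table(default_params(), lt)
  expect_equal(eval_age_curve(p$bg_mortality, 65), 0.01)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(lt, f, row.names = FALSE)
  expect_equal(set_life_table(default_params(), f), p)
  expect_error(set_life_table(default_params(), data.frame(age = 1)),
               "columns")
})

test_that("beta fits match the point and the reported 95% range", {
  d <- fit_psa_distribution(prob_estimate(0.6268, 0.4624, 0.8105))
  expect_identical(d$family, "beta")
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.6268, tolerance = 1e-3)
  expect_lt(abs(qbeta(0.025, d$shape1, d$shape2) - 0.4624), 0.02)
  expect_lt(abs(qbeta(0.975, d$shape1, d$shape2) - 0.8105), 0.02)
  # Monte Carlo check of the sampler itself
  x <- local({set.seed(1); sample_psa_distribution(d, 1e5)})
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.6268), 3 * sd(x) / sqrt(1e5))
  expect_lt(abs(quantile(x, 0.025) - 0.4624), 0.02)
  expect_lt(abs(quantile(x, 0.975) - 0.8105), 0.02)
})

test_that("degenerate and boundary estimates give point masses", {
  d <- fit_psa_distribution(prob_estimate(0.0010))
  expect_identical(d$family, "point")
  expect_identical(sample_psa_distribution(d, 3), rep(0.0010, 3))
  expect_identical(fit_psa_distribution(prob_estimate(0))$family, "point")
  expect_identical(
    fit_psa_distribution(prob_estimate(1, 0.5, 1))$family, "point")
})

test_that("infeasible beta fits fall back to uniform with a warning", {
  # mean far into the lower end of a wide skewed range: no beta with this
  # mean reproduces the quantiles
  est <- prob_estimate(0.1844, 0.1451, 0.4285)
  expect_warning(d <- fit_psa_distribution(est), "Uniform")
  expect_identical(d$family, "uniform")
  x <- local({set.seed(2); sample_psa_distribution(d, 1e4)})
  expect_true(all(x >= est$low & x <= est$high))
})

test_that("every packaged distribution samples in [0,1] with the right mean", {
  p <- default_params()
  fields <- c("mort_sabr", "mort_progression", "p_prog_lob", "p_prog_sabr",
              "frac_rr_lob", "p_salv_rr_lob", "p_salv_rr_sabr",
              "p_prog_post_salv_rr_lob", "p_prog_post_salv_rr_sabr")
  set.seed(3)
  for (f in fields) {
    d <- suppressWarnings(fit_psa_distribution(p[[f]]))
    x <- sample_psa_distribution(d, 2e4)
    expect_true(all(x >= 0 & x <= 1), label = f)
    tol <- max(3 * sd(x) / sqrt(2e4), 0.05 * (p[[f]]$high - p[[f]]$low))
    expect_lt(abs(mean(x) - d$mean), tol)
  }
})
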