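test_that("state spaces have 9 lobectomy and 13 SABR states, 22 distinct", {
  lob <- health_states("lobectomy")
  sabr <- health_states("sabr")
  expect_identical(nrow(lob), 9L)
  expect_identical(nrow(sabr), 13L)
  expect_identical(
    length(unique(c(paste0("lob.", lob$name), paste0("sabr.", sabr$name)))),
    22L)
  # exactly one absorbing death state per arm, and the persistent states
  # (NED-type, progression, death) are the only non-tunnel ones
  for (df in list(lob, sabr)) {
    expect_identical(df$name[df$absorbing], "death")
    expect_setequal(df$name[!df$tunnel],
                    grep("^ned|progression|death", df$name, value = TRUE))
  }
  expect_error(health_states("surgery"), "arg")
})

test_that("every transition row is a distribution with death floored by background mortality", {
  p <- default_params()
  for (arm in c("lobectomy", "sabr")) {
    st <- health_states(arm)
    for (age in 45:100) {
      M <- transition_matrix(arm, age, p)
      expect_true(all(abs(rowSums(M) - 1) < 1e-12),
                  label = sprintf("%s rows sum to 1 at age %d", arm, age))
      expect_true(all(M >= 0 & M <= 1))
      # death absorbs
      expect_identical(unname(M["death", "death"]), 1)
      expect_true(all(M["death", colnames(M) != "death"] == 0))
      # alive persistent/tunnel states carry at least the background hazard
      bg <- eval_age_curve(p$bg_mortality, age)
      alive <- st$name[!st$absorbing & !st$transient]
      expect_true(all(M[alive, "death"] >= bg - 1e-15),
                  label = sprintf("%s death floor at age %d", arm, age))
    }
  }
})

test_that("NED rows match the closed-form competing-risk oracle", {
  p <- default_params()
  row <- transition_row("sabr", "ned", 85, p)
  # independent risks: stay = (1 - bg(85)) (1 - p_prog_sabr)
  expect_equal(unname(row["ned"]), (1 - 0.082156) * (1 - 0.0790))
  expect_equal(1 - unname(row["ned"]),
               1 - (1 - 0.082156) * (1 - 0.0790))
  # lobectomy recurrences have no local-only component
  row <- transition_row("lobectomy", "ned", 60, p)
  expect_identical(sum(row[grep("lr", names(row))]), 0)
  # all recurrence routes land in persistent states within the cycle:
  # transient event states never receive occupancy
  tr <- run_cohort("sabr", 55, p)
  transient <- tr$states$name[tr$states$transient]
  expect_true(all(tr$occupancy[, transient] == 0))
})

test_that("immortal and certain-death limits behave exactly", {
  p <- immortal_params()
  tr <- run_cohort("lobectomy", 45, p)
  expect_equal(tr$alive, rep(1, tr$horizon + 1))
  expect_equal(life_expectancy(tr), tr$horizon)  # all-alive trapezoid
  p2 <- default_params()
  p2$mort_lobectomy <- age_curve(45, 1, kind = "linear")
  tr2 <- run_cohort("lobectomy", 60, p2)
  expect_equal(tr2$alive, c(1, rep(0, tr2$horizon)))
  expect_equal(life_expectancy(tr2), 0.5)  # death halfway through cycle 1
})

test_that("cohort traces conserve probability and death is monotone", {
  p <- default_params()
  for (arm in c("lobectomy", "sabr")) for (age in c(45, 70, 85)) {
    tr <- run_cohort(arm, age, p)
    expect_identical(nrow(tr$occupancy), tr$horizon + 1L)
    expect_equal(unname(tr$occupancy[1, "initial"]), 1)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
    expect_equal(tr$attained_age, age + 0:tr$horizon)
    expect_identical(run_cohort(arm, age, p)$occupancy, tr$occupancy)
  }
  expect_error(run_cohort("lobectomy", 30), "45")
})

test_that("life expectancy equals the exhaustive path-enumeration oracle", {
  p <- set_params(default_params(), n_cycles = 2L)  # 3 transitions in all
  for (arm in c("lobectomy", "sabr")) for (age in c(45, 75, 85)) {
    le <- life_expectancy(run_cohort(arm, age, p))
    expect_equal(le, enum_le_oracle(arm, age, p), tolerance = 1e-10,
                 label = sprintf("%s age %d", arm, age))
  }
  # and on a perturbed parameter table
  p2 <- set_params(make_parameter_table(fixture_spec(seed = 9, jitter = 1)),
                   n_cycles = 3L)
  expect_equal(life_expectancy(run_cohort("sabr", 70, p2)),
               enum_le_oracle("sabr", 70, p2), tolerance = 1e-10)
})

test_that("survival extraction reads and interpolates the trace", {
  tr <- run_cohort("lobectomy", 45)
  expect_equal(survival_at(tr, 0), 1)
  expect_equal(survival_at(tr, 5), tr$alive[6])
  expect_equal(survival_at(tr, 4.5), (tr$alive[5] + tr$alive[6]) / 2)
  s <- survival_at(tr, seq(0, tr$horizon, by = 0.25))
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(survival_at(tr, tr$horizon + 1), "horizon")
  expect_error(survival_at(tr, -0.1), "horizon")
  expect_equal(predict(tr, c(0, 5)), survival_at(tr, c(0, 5)))
})

test_that("raising any mortality or progression probability never raises life expectancy", {
  p <- default_params()
  base <- c(lobectomy = life_expectancy(run_cohort("lobectomy", 70, p)),
            sabr = life_expectancy(run_cohort("sabr", 70, p)))
  bump_fields <- c("mort_sabr", "mort_conv_rt", "mort_progression",
                   "p_prog_lob", "p_prog_sabr", "p_prog_post_salv_lr_sabr",
                   "p_prog_post_salv_rr_lob", "p_prog_post_salv_rr_sabr")
  for (f in bump_fields) {
    q <- p
    q[[f]] <- prob_estimate(min(1, p[[f]]$point + 0.1))
    for (arm in c("lobectomy", "sabr"))
      expect_lte(life_expectancy(run_cohort(arm, 70, q)),
                 base[[arm]] + 1e-12, label = sprintf("%s after %s", arm, f))
  }
  # age-curve mortality too
  for (f in c("bg_mortality", "mort_lobectomy")) {
    q <- p
    q[[f]] <- age_curve(p[[f]]$ages, pmin(p[[f]]$values * 1.5, 1),
                        kind = p[[f]]$kind)
    for (arm in c("lobectomy", "sabr"))
      expect_lte(life_expectancy(run_cohort(arm, 70, q)),
                 base[[arm]] + 1e-12, label = sprintf("%s after %s", arm, f))
  }
})

test_that("arms with equalized parameters have identical life expectancy", {
  p <- symmetric_params()
  for (age in c(45, 65, 85))
    expect_equal(life_expectancy(run_cohort("lobectomy", age, p)),
                 life_expectancy(run_cohort("sabr", age, p)),
                 tolerance = 1e-9)
})

test_that("trace export carries states, alive fraction and attained age", {
  tr <- run_cohort("sabr", 75)
  df <- as.data.frame(tr)
  expect_identical(nrow(df), tr$horizon + 1L)
  expect_true(all(c("cycle", "ned", "progression", "death", "alive",
                    "attained_age") %in% names(df)))
  expect_equal(df$alive, 1 - df$death)
  out <- capture.output(print(summary(tr)))
  expect_true(any(grepl("Life expectancy", out)))
})
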