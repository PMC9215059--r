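test_that("truncation scenario moves mass at or above the threshold downward", {
  b <- make_prev(c(0.40, 0.30, 0.20, 0.10))
  out <- apply_scenario(b, scenario_truncate(35), default_schema)
  expect_equal(out$prevalence$proportion, c(0.40, 0.30, 0.30, 0.00))
  # mass conserved
  expect_equal(sum(out$prevalence$proportion), 1)
  # reallocating to the reference instead
  ref <- apply_scenario(b, scenario_truncate(35, "reference"), default_schema)
  expect_equal(ref$prevalence$proportion, c(0.50, 0.30, 0.20, 0.00))
  # threshold 30 eliminates the top two categories
  t30 <- apply_scenario(b, scenario_truncate(30), default_schema)
  expect_equal(t30$prevalence$proportion, c(0.40, 0.60, 0.00, 0.00))
})

test_that("truncation with no mass above the threshold is a warned no-op", {
  b <- make_prev(c(0.5, 0.5, 0, 0))
  out <- apply_scenario(b, scenario_truncate(35), default_schema)
  expect_equal(out$prevalence$proportion, c(0.5, 0.5, 0, 0))
  expect_false(out$noop)  # categories existed; they just held no mass
  # threshold above every category: warning + unchanged table
  expect_warning(
    out2 <- apply_scenario(b, scenario_truncate(100), default_schema),
    "unchanged")
  expect_true(out2$noop)
  expect_equal(out2$prevalence$proportion, b$proportion)
  # threshold below every category is an error
  sch_pos <- bmi_schema()
  expect_error(apply_scenario(b, scenario_truncate(-1), sch_pos), "positive")
})

test_that("hold and tmrel scenarios produce the stated distributions", {
  b <- make_prev(c(0.40, 0.30, 0.20, 0.10))
  held <- apply_scenario(b, scenario_hold(), default_schema)
  expect_equal(held$prevalence$proportion, b$proportion)
  tm <- apply_scenario(b, scenario_tmrel(), default_schema)
  expect_equal(tm$prevalence$proportion, c(1, 0, 0, 0))
  # target requires a table and a matching layout
  expect_error(scenario_target(), "prevalence_table")
  other <- make_prev(c(0.6, 0.4), stratum = "M",
                     schema = bmi_schema(c("<25", ">=25"), c(0, 25),
                                         c(25, Inf), c(22, 30)))
  expect_error(apply_scenario(b, scenario_target(other), default_schema),
               "share strata")
})

test_that("mean-shift scenario lowers exposed medians, not prevalences", {
  b <- make_prev(c(0.40, 0.30, 0.20, 0.10))
  out <- apply_scenario(b, scenario_mean_shift(1, 25), default_schema)
  expect_equal(out$prevalence$proportion, b$proportion)
  expect_equal(out$schema$median, c(22, 26, 31, 36))
  # reference category median untouched; bounds untouched
  expect_equal(out$schema$lower, default_schema$lower)
  # shift of 2 limited to BMI >= 30
  s2 <- shift_schema_medians(default_schema, 2, 30)
  expect_equal(s2$median, c(22, 27, 30, 35))
})

test_that("scenario outputs always satisfy the simplex constraint", {
  set.seed(71)
  specs <- list(scenario_tmrel(), scenario_hold(), scenario_truncate(35),
                scenario_truncate(30, "reference"), scenario_mean_shift())
  for (i in 1:25) {
    p <- as.vector(rmultinom(1, 1000, runif(4))) / 1000
    b <- make_prev(p)
    for (sp in specs) {
      out <- suppressWarnings(apply_scenario(b, sp, default_schema))
      expect_true(all(out$prevalence$proportion >= 0))
      expect_equal(sum(out$prevalence$proportion), 1, tolerance = 1e-9)
    }
  }
})

test_that("prevalence projection extrapolates linearly, clips and renormalises", {
  sch2 <- bmi_schema(c("<25", ">=25"), c(0, 25), c(25, Inf), c(22, 30))
  e <- make_prev(c(0.50, 0.50), schema = sch2, year = 2008)
  l <- make_prev(c(0.40, 0.60), schema = sch2, year = 2019)
  # 11 further years continue the straight line
  out <- project_prevalence(e, l, 2030)
  expect_equal(out$proportion, c(0.30, 0.70))
  expect_equal(unique(out$year), 2030)
  # target at the late year returns the late table unchanged
  expect_equal(project_prevalence(e, l, 2019)$proportion, l$proportion)
  # constant inputs project constantly
  expect_equal(project_prevalence(
    make_prev(c(0.4, 0.6), schema = sch2, year = 2008),
    make_prev(c(0.4, 0.6), schema = sch2, year = 2019), 2040)$proportion,
    c(0.4, 0.6))
  # a trend that would cross 0 is clipped then renormalised to sum 1
  e2 <- make_prev(c(0.10, 0.90), schema = sch2, year = 2008)
  l2 <- make_prev(c(0.02, 0.98), schema = sch2, year = 2019)
  far <- project_prevalence(e2, l2, 2040)
  expect_true(all(far$proportion >= 0))
  expect_equal(sum(far$proportion), 1)
  # mismatched layouts and bad year ordering are rejected
  expect_error(project_prevalence(l, e, 2030), "early year")
  e3 <- make_prev(c(0.5, 0.5), stratum = "M", schema = sch2, year = 2008)
  expect_error(project_prevalence(e3, l, 2030), "share strata")
})
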