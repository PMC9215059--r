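test_that("generation is bit-for-bit reproducible under a fixed seed", {
  cfg <- synthetic_config(seed = 123)
  expect_identical(generate_prevalence(cfg), generate_prevalence(cfg))
  expect_identical(generate_cost_series(cfg), generate_cost_series(cfg))
  # a different seed changes the draws
  cfg2 <- synthetic_config(seed = 124)
  expect_false(identical(generate_prevalence(cfg)$proportion,
                         generate_prevalence(cfg2)$proportion))
})

test_that("generated prevalence tables partition the effective sample size", {
  cfg <- synthetic_config(seed = 7, effective_n = c(F = 1234, M = 777))
  prev <- generate_prevalence(cfg)
  for (s in c("F", "M")) {
    p <- prev$proportion[prev$stratum == s]
    n <- unique(prev$effective_n[prev$stratum == s])
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(abs(p * n - round(p * n)) < 1e-9))  # counts are integers
    expect_true(all(p >= 0 & p <= 1))
  }
  # per-category binomial CIs bracket the observed proportions
  expect_true(all(prev$ci_low <= prev$proportion + 1e-12 &
                  prev$proportion <= prev$ci_high + 1e-12))
})

test_that("a degenerate truth is reproduced exactly at any seed", {
  for (seed in c(1, 99)) {
    cfg <- synthetic_config(seed = seed, strata = "F",
                            true_proportions = list(F = c(1, 0, 0, 0)),
                            effective_n = c(F = 50))
    expect_equal(generate_prevalence(cfg)$proportion, c(1, 0, 0, 0))
  }
})

test_that("observed proportions converge to the truth at large effective n", {
  truth <- c(0.4, 0.3, 0.2, 0.1)
  cfg <- synthetic_config(seed = 2, strata = "F",
                          true_proportions = list(F = truth),
                          effective_n = c(F = 1e6))
  prev <- generate_prevalence(cfg)
  # binomial bound: 3 * sqrt(p(1-p)/n) < 0.005 for every category
  expect_true(all(abs(prev$proportion - truth) <
                  pmax(3 * sqrt(truth * (1 - truth) / 1e6), 0.005)))
  expect_lt(max(abs(prev$proportion - truth)), 0.005)
})

test_that("cost series follow the configured linear trend", {
  trend <- data.frame(cancer = "site_a", sex = "F",
                      intercept = 100, slope = 10, sd = 0)
  cfg <- synthetic_config(seed = 3, cost_trend = trend)
  cs <- generate_cost_series(cfg)
  expect_equal(cs$cost[cs$year == 2019], 210)  # 100 + 10 * 11, no noise
  expect_equal(cs$cost, 100 + 10 * (cs$year - 2008))
  # zero slope gives a constant series
  cfg0 <- synthetic_config(seed = 3, cost_trend = transform(trend, slope = 0))
  expect_equal(unique(generate_cost_series(cfg0)$cost), 100)
})

test_that("mean of noisy replicate series matches the noiseless value (CLT bound)", {
  trend <- data.frame(cancer = "site_a", sex = "F",
                      intercept = 100, slope = 10, sd = 5)
  finals <- vapply(1:500, function(i) {
    cfg <- synthetic_config(seed = i, cost_trend = trend)
    cs <- generate_cost_series(cfg)
    cs$cost[cs$year == 2019]
  }, numeric(1))
  expect_lt(abs(mean(finals) - 210), 3 * 5 / sqrt(500))
})

test_that("ground-truth PIF evaluates the deterministic formula on the truth", {
  sch2 <- bmi_schema(c("<25", ">=25"), c(0, 25), c(25, Inf), c(22, 27))
  rr2 <- data.frame(cancer = "c", sex = "F", increment = 1,
                    rr = 2^(1 / 5), ci_low = 2^(1 / 5), ci_high = 2^(1 / 5))
  # rr1 chosen so rr at the exposed category (gap 5) is exactly 2
  cfg <- synthetic_config(seed = 1, strata = "F", schema = sch2,
                          true_proportions = list(F = c(0.5, 0.5)),
                          effective_n = c(F = 100), rr_table = rr2,
                          cost_trend = data.frame(cancer = "c", sex = "F",
                                                  intercept = 1, slope = 1,
                                                  sd = 0))
  # truth (0.5, 0.5), RR (1, 2), all-reference counterfactual: (1.5-1)/1.5
  expect_equal(ground_truth_pif(cfg, scenario_tmrel(), "c", "F"), 1 / 3,
               tolerance = 1e-12)
  # holding at baseline gives 0
  expect_equal(ground_truth_pif(cfg, scenario_hold(), "c", "F"), 0)
  # all mass already in the reference category: 0 under truncation
  cfg_ref <- synthetic_config(seed = 1, strata = "F", schema = sch2,
                              true_proportions = list(F = c(1, 0)),
                              effective_n = c(F = 100), rr_table = rr2,
                              cost_trend = data.frame(cancer = "c", sex = "F",
                                                      intercept = 1, slope = 1,
                                                      sd = 0))
  expect_equal(ground_truth_pif(cfg_ref, scenario_truncate(25), "c", "F"), 0)
  expect_error(ground_truth_pif(cfg, scenario_tmrel(), "nope", "F"), "no unique RR")
})

test_that("synthetic datasets round-trip through the CSV/YAML writers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 5)
  paths <- write_synthetic_dataset(cfg, dir)
  expect_true(all(file.exists(paths)))
  prev <- read_prevalence_csv(paths[["prevalence"]])
  expect_equal(prev$proportion, generate_prevalence(cfg)$proportion)
  rr <- read_rr_csv(paths[["rr"]])
  expect_s3_class(rr, "rr_table")
  cs <- read_cost_csv(paths[["costs"]])
  expect_equal(cs$cost, generate_cost_series(cfg)$cost)
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$seed, 5L)
  y <- yaml::read_yaml(paths[["config"]])
  expect_equal(y$seed, 5L)
  expect_equal(unlist(y$true_proportions$F), cfg$true_proportions$F)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(synthetic_config(true_proportions = list(F = c(0.5, 0.4, 0.05, 0.04),
                                                        M = c(0.25, 0.25, 0.25, 0.25))),
               "sum to 1")
  expect_error(synthetic_config(effective_n = c(F = 0, M = 10)), ">= 1")
  expect_error(synthetic_config(years = 2019), ">= 2")
  expect_error(synthetic_config(cost_trend = data.frame(
    cancer = "a", sex = "F", intercept = 1, slope = 1, sd = -1)), "sd")
})
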