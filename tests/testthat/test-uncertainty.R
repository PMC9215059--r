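test_that("log-RR standard error back-calculation matches longhand evaluation", {
  # (ln 1.59 - ln 1.42) / (2 * 1.959964)
  expect_equal(rr_log_se(1.42, 1.59),
               (log(1.59) - log(1.42)) / (2 * 1.959964), tolerance = 1e-15)
  expect_equal(round(rr_log_se(1.42, 1.59), 6), 0.028847)
  expect_equal(rr_log_se(1.3, 1.3), 0)
  expect_error(rr_log_se(1.5, 1.2), "ci_low <= ci_high")
})

test_that("RR draws are centred on the log point estimate", {
  set.seed(3)
  tab <- rr_row(1.50, 1.42, 1.59)
  draws <- replicate(200, draw_log_rr(tab)$rr)
  se <- rr_log_se(1.42, 1.59)
  expect_lt(abs(mean(log(draws)) - log(1.50)), 3 * se / sqrt(200))
  # zero-variance CI collapses every draw to the point estimate
  expect_equal(draw_log_rr(rr_row(1.3))$rr, 1.3)
})

test_that("prevalence draws respect the simplex and shrink with effective n", {
  set.seed(5)
  p <- c(0.42, 0.34, 0.16, 0.08)
  b_small <- make_prev(p, effective_n = 500)
  d <- draw_prevalence(b_small)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  expect_true(all(d$proportion >= 0))
  # degenerate proportions are reproduced exactly
  b_deg <- make_prev(c(1, 0, 0, 0), effective_n = 100)
  expect_equal(draw_prevalence(b_deg)$proportion, c(1, 0, 0, 0))
  # binomial variance vanishes as effective n grows (tested at 1e8)
  b_big <- make_prev(p, effective_n = 1e8)
  d_big <- draw_prevalence(b_big)
  expect_lt(max(abs(d_big$proportion - p)), 1e-3)
  # fixed seed reproduces the draw sequence
  set.seed(17); a1 <- draw_prevalence(b_small)
  set.seed(17); a2 <- draw_prevalence(b_small)
  expect_identical(a1, a2)
  # multinomial mode partitions effective_n exactly
  dm <- draw_prevalence(b_small, mc_config(prevalence_resampling = "multinomial"))
  expect_equal(sum(dm$proportion * 500), 500, tolerance = 1e-9)
  expect_error(draw_prevalence(make_prev(p)), "effective_n")
})

test_that("simulate_pif collapses to the deterministic PIF at zero variance", {
  p <- c(0.42, 0.34, 0.16, 0.08)
  b <- make_prev(p, effective_n = Inf)
  r <- rr_row(1.5, cancer = "c")
  pe <- simulate_pif(b, scenario_tmrel(), r, default_schema,
                     mc_config(200, seed = 1))
  det <- pe$deterministic
  expect_equal(pe$point, det, tolerance = 1e-12)
  expect_equal(pe$ci_low, det, tolerance = 1e-12)
  expect_equal(pe$ci_high, det, tolerance = 1e-12)
  # and the deterministic value matches the direct formula
  rr_c <- c(1, 1.5^1, 1.5^2, 1.5^3)  # rr1 = 1.5^(1/5), gaps 0/5/10/15
  expect_equal(det, (sum(p * rr_c) - 1) / sum(p * rr_c), tolerance = 1e-12)
})

test_that("simulate_pif is deterministic under a fixed seed and truncates at 0", {
  b <- make_prev(c(0.42, 0.34, 0.16, 0.08), effective_n = 2000)
  r <- rr_row(1.5, 1.42, 1.59)
  a <- simulate_pif(b, scenario_tmrel(), r, default_schema, mc_config(500, seed = 9))
  b2 <- simulate_pif(b, scenario_tmrel(), r, default_schema, mc_config(500, seed = 9))
  expect_identical(a, b2)
  expect_true(a$ci_low >= 0 && a$ci_low <= a$point && a$point <= a$ci_high)
  # a null-effect RR with wide CI produces many negative draws; with
  # truncation on they are rounded to 0, so the lower bound is exactly 0
  r0 <- rr_row(1.0, 0.9, 1.11)
  pe0 <- simulate_pif(b, scenario_tmrel(), r0, default_schema,
                      mc_config(1000, seed = 4))
  expect_gt(pe0$n_truncated, 0)
  expect_equal(pe0$ci_low, 0)
  # with truncation off the draws keep their sign
  pe_raw <- simulate_pif(b, scenario_tmrel(), r0, default_schema,
                         mc_config(1000, seed = 4, truncate_negative = FALSE))
  expect_lt(pe_raw$ci_low, 0)
  expect_equal(pe_raw$n_truncated, 0L)
})

test_that("hold-at-baseline counterfactual gives all-zero PIF draws", {
  b <- make_prev(c(0.42, 0.34, 0.16, 0.08), effective_n = 1000)
  r <- rr_row(1.5, 1.42, 1.59)
  pe <- simulate_pif(b, scenario_hold(), r, default_schema, mc_config(300, seed = 2))
  expect_equal(pe$point, 0)
  expect_equal(pe$ci_high, 0)
})

test_that("with shrinking input variance the median converges to the deterministic PIF", {
  p <- c(0.42, 0.34, 0.16, 0.08)
  r_narrow <- rr_row(1.5, 1.4999, 1.5001)
  b_tight <- make_prev(p, effective_n = 1e7)
  pe <- simulate_pif(b_tight, scenario_tmrel(), r_narrow, default_schema,
                     mc_config(2000, seed = 8, truncate_negative = FALSE))
  expect_equal(pe$point, pe$deterministic, tolerance = 1e-3)
})

test_that("Monte Carlo error of the median shrinks like 1/sqrt(n)", {
  b <- make_prev(c(0.42, 0.34, 0.16, 0.08), effective_n = 3000)
  r <- rr_row(1.5, 1.42, 1.59)
  set.seed(33)
  meds <- function(n_iter, reps) {
    vapply(seq_len(reps), function(i)
      simulate_pif(b, scenario_tmrel(), r, default_schema,
                   mc_config(n_iter))$point, numeric(1))
  }
  sd_small <- sd(meds(200, 40))
  sd_large <- sd(meds(1800, 40))
  # 9x the iterations should shrink the sd about 3-fold
  expect_lt(sd_large, sd_small / 1.6)
})

test_that("mean-shift Monte Carlo PIF matches its deterministic value with tight inputs", {
  p <- c(0.42, 0.34, 0.16, 0.08)
  b <- make_prev(p, effective_n = Inf)
  r <- rr_row(1.5)
  pe <- simulate_pif(b, scenario_mean_shift(1, 25), r, default_schema,
                     mc_config(100, seed = 6))
  rr1 <- 1.5^(1 / 5)
  num <- sum(p * rr1^c(0, 5, 10, 15)) - sum(p * rr1^c(0, 4, 9, 14))
  expect_equal(pe$point, num / sum(p * rr1^c(0, 5, 10, 15)), tolerance = 1e-12)
})
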