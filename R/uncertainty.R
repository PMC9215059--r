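#' Monte Carlo configuration
#'
#' Settings for uncertainty propagation through the PIF pipeline.
#'
#' @param n_iterations number of Monte Carlo iterations (default 10,000).
#' @param seed optional integer seed; when given, each simulation call is
#'   reproducible on its own.
#' @param percentiles percentiles (in percent, strictly increasing within
#'   (0, 100)) summarising the draws; the middle one is the central
#'   estimate. Default `c(2.5, 50, 97.5)`.
#' @param truncate_negative round negative PIF draws to 0 (default `TRUE`),
#'   on the assumption that reducing BMI cannot increase cancer risk.
#' @param prevalence_resampling `"binomial"` (per-category binomial draws
#'   renormalised to sum to 1) or `"multinomial"` (a single partition of the
#'   effective sample size).
#' @return A list of class `"mc_config"`.
#' @export
mc_config <- function(n_iterations = 10000L, seed = NULL,
                      percentiles = c(2.5, 50, 97.5),
                      truncate_negative = TRUE,
                      prevalence_resampling = c("binomial", "multinomial")) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (length(percentiles) != 3 || any(diff(percentiles) <= 0) ||
      any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must be 3 strictly increasing values in (0, 100)",
         call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations), seed = seed,
                 percentiles = percentiles,
                 truncate_negative = isTRUE(truncate_negative),
                 prevalence_resampling = match.arg(prevalence_resampling)),
            class = "mc_config")
}

# z-quantile used to back-calculate log-scale SEs from 95% CIs
Z975 <- 1.959964

#' Log-scale standard error implied by a 95% confidence interval
#'
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param ci_low,ci_high positive CI bounds, `ci_low <= ci_high`.
#' @return Standard error on the log scale (0 when the bounds coincide).
#' @examples
#' rr_log_se(1.42, 1.59)  # 0.028884...
#' @export
rr_log_se <- function(ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high < ci_low))
    stop("need 0 < ci_low <= ci_high", call. = FALSE)
  (log(ci_high) - log(ci_low)) / (2 * Z975)
}

# n_iter x k matrix of prevalence draws; rows sum to 1.
# effective_n = Inf gives degenerate (noise-free) draws.
draw_prevalence_matrix <- function(p, effective_n, n_iter, mode = "binomial") {
  k <- length(p)
  if (is.na(effective_n)) stop("effective_n is required for prevalence draws",
                               call. = FALSE)
  if (is.infinite(effective_n))
    return(matrix(p, nrow = n_iter, ncol = k, byrow = TRUE))
  if (effective_n < 1) stop("effective_n must be >= 1", call. = FALSE)
  if (mode == "multinomial") {
    m <- t(stats::rmultinom(n_iter, size = effective_n, prob = p)) / effective_n
  } else {
    m <- matrix(stats::rbinom(n_iter * k, size = effective_n,
                              prob = rep(p, each = n_iter)) / effective_n,
                nrow = n_iter, ncol = k)
    rs <- rowSums(m)
    bad <- rs == 0
    if (any(bad)) {  # all-zero draw (only possible at tiny effective_n)
      m[bad, ] <- matrix(p, nrow = sum(bad), ncol = k, byrow = TRUE)
      rs[bad] <- 1
    }
    m <- m / rs
  }
  colnames(m) <- names(p)
  m
}

#' Draw a resampled prevalence table
#'
#' One Monte Carlo draw of a prevalence table: each category proportion is
#' replaced by `Binomial(effective_n, P_i) / effective_n` and the stratum is
#' renormalised to sum to 1 (default), or a single multinomial partition of
#' `effective_n` is drawn.
#'
#' @param table a [prevalence_table()] with `effective_n` set.
#' @param config an [mc_config()] (only the resampling mode is used).
#' @return A `prevalence_table` with resampled proportions.
#' @export
draw_prevalence <- function(table, config = mc_config()) {
  table <- validate_prevalence(table)
  out <- table
  for (s in unique(table$stratum)) {
    idx <- which(table$stratum == s)
    n_eff <- unique(table$effective_n[idx])
    if (length(n_eff) != 1L)
      stop("effective_n must be constant within a stratum", call. = FALSE)
    out$proportion[idx] <- draw_prevalence_matrix(
      table$proportion[idx], n_eff, 1L, config$prevalence_resampling)[1, ]
  }
  out$ci_low <- NA_real_; out$ci_high <- NA_real_
  validate_prevalence(out)
}

#' Draw a relative risk from its log-normal sampling distribution
#'
#' One Monte Carlo draw of each RR in a table: the log-RR is drawn from
#' `Normal(log(rr), se)` with `se` back-calculated from the 95% CI (see
#' [rr_log_se()]). The draw is made on the published per-increment scale;
#' rescaling and categorical expansion are applied per draw downstream.
#'
#' @param table an [rr_table()].
#' @return An `rr_table` whose `rr` holds the draws (CI bounds collapsed to
#'   the draw).
#' @export
draw_log_rr <- function(table) {
  table <- validate_rr_table(table)
  se <- rr_log_se(table$ci_low, table$ci_high)
  draw <- exp(stats::rnorm(nrow(table), mean = log(table$rr), sd = se))
  out <- table
  out$rr <- draw; out$ci_low <- draw; out$ci_high <- draw
  out
}

#' Monte Carlo potential impact fraction
#'
#' Propagates sampling uncertainty through the PIF computation for one
#' cancer subtype, sex stratum and counterfactual scenario. Each iteration
#' draws (a) the baseline category prevalences from binomial (renormalised)
#' or multinomial distributions at the stratum's effective sample size and
#' (b) the log relative risk per published increment from a normal
#' distribution, expands the drawn RR over the BMI categories, applies the
#' scenario, and evaluates [pif_subtype()]. One RR draw per iteration is
#' shared across categories (all categorical RRs derive from the same
#' dose-response coefficient). Scenario counterfactuals that are functions
#' of the baseline (truncation, mean shift, hold-at-baseline) are applied to
#' each draw; fixed target distributions stay fixed. Negative draws are
#' rounded to 0 when `config$truncate_negative`.
#'
#' @param baseline a [prevalence_table()] for a single stratum, with
#'   `effective_n` (`Inf` for a noise-free prevalence).
#' @param scenario an `ebw_scenario` (see [scenarios]).
#' @param rr a one-row [rr_table()] on its published increment, with 95% CI.
#' @param schema a [bmi_schema()].
#' @param config an [mc_config()].
#' @return A list of class `"pif_estimate"`: `point` (middle percentile),
#'   `ci_low`, `ci_high`, `deterministic` (PIF at the observed inputs),
#'   `n_draws`, `n_truncated`, `cancer`, `sex`, `scenario`.
#' @examples
#' b <- prevalence_table(rep("F", 4), c("<25", "25-30", "30-35", ">=35"),
#'                       c(0.45, 0.30, 0.17, 0.08), effective_n = 30000)
#' r <- rr_table("endometrium", "F", 5, 1.50, 1.42, 1.59)
#' simulate_pif(b, scenario_tmrel(), r, bmi_schema(),
#'              mc_config(n_iterations = 1000, seed = 1))
#' @export
simulate_pif <- function(baseline, scenario, rr, schema, config = mc_config()) {
  assert_schema(schema)
  baseline <- validate_prevalence(baseline)
  rr <- validate_rr_table(rr)
  if (nrow(rr) != 1L) stop("rr must be a single-row rr_table", call. = FALSE)
  if (length(unique(baseline$stratum)) != 1L)
    stop("baseline must hold a single stratum", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  stratum <- baseline$stratum[1]
  p <- stratum_proportions(baseline, stratum, schema)
  n_eff <- unique(baseline$effective_n)
  n <- config$n_iterations
  k <- nrow(schema)
  expo <- schema$median - reference_median(schema)

  # deterministic PIF at the observed inputs
  det <- deterministic_pif(p, scenario, rr, schema)

  P <- draw_prevalence_matrix(p, n_eff, n, config$prevalence_resampling)
  se <- rr_log_se(rr$ci_low, rr$ci_high)
  log_rr1 <- stats::rnorm(n, mean = log(rr$rr), sd = se) / rr$increment
  RR <- exp(outer(log_rr1, expo))                      # n x k
  base_term <- rowSums(P * RR)

  cf_term <- switch(scenario$kind,
    tmrel = rep(1, n),
    target = as.vector(RR %*% fixed_cf(scenario$table, stratum, schema)),
    hold = if (is.null(scenario$table)) base_term
           else as.vector(RR %*% fixed_cf(scenario$table, stratum, schema)),
    truncate = {
      Tm <- truncation_matrix(schema, scenario)
      rowSums((P %*% Tm) * RR)
    },
    mean_shift = {
      cf_schema <- shift_schema_medians(schema, scenario$shift,
                                        scenario$eligible_min)
      expo_cf <- cf_schema$median - reference_median(cf_schema)
      rowSums(P * exp(outer(log_rr1, expo_cf)))
    },
    stop("unknown scenario kind: ", scenario$kind, call. = FALSE))

  draws <- (base_term - cf_term) / base_term
  n_trunc <- 0L
  if (config$truncate_negative) {
    n_trunc <- sum(draws < 0)
    draws[draws < 0] <- 0
  }
  q <- unname(stats::quantile(draws, probs = config$percentiles / 100))
  structure(list(point = q[2], ci_low = q[1], ci_high = q[3],
                 deterministic = det, n_draws = n, n_truncated = n_trunc,
                 cancer = rr$cancer, sex = rr$sex, scenario = scenario$label),
            class = "pif_estimate")
}

# PIF at the observed (undrawn) inputs, shared by simulate_pif and the
# synthetic ground-truth oracle
deterministic_pif <- function(p, scenario, rr, schema) {
  rr1 <- rescale_rr(rr, 1)
  prof <- categorical_profile(rr1, schema)
  rr_vec <- profile_vector(prof, rr$cancer[1], rr$sex[1], schema)
  tab <- prevalence_table(stratum = rep("s", length(p)),
                          category = names(p), proportion = unname(p))
  app <- suppressWarnings(apply_scenario(tab, scenario, schema))
  p_cf <- stratum_proportions(app$prevalence, "s", schema)
  rr_cf <- if (identical(app$schema, schema)) rr_vec else
    profile_vector(categorical_profile(rr1, app$schema), rr$cancer[1],
                   rr$sex[1], app$schema)
  pif_subtype(p, p_cf, rr_vec, rr_cf)
}

fixed_cf <- function(table, stratum, schema) {
  st <- if (stratum %in% table$stratum) stratum else unique(table$stratum)[1]
  stratum_proportions(table, st, schema)
}

# k x k matrix moving mass from eliminated categories into the destination
truncation_matrix <- function(schema, scenario) {
  k <- nrow(schema)
  elim <- schema$lower >= scenario$threshold
  keep <- which(!elim)
  if (length(keep) == 0L) stop("threshold excludes every category", call. = FALSE)
  dest <- if (scenario$reallocate_to == "reference") which(schema$reference)
          else keep[length(keep)]
  Tm <- diag(k)
  for (j in which(elim)) {
    Tm[j, j] <- 0
    Tm[j, dest] <- 1
  }
  Tm
}

#' @export
print.pif_estimate <- function(x, ...) {
  cat(sprintf("PIF %s/%s [%s]: %.2f%% (95%% UI %.2f-%.2f), %d draws, %d truncated\n",
              x$cancer, x$sex, x$scenario, 100 * x$point, 100 * x$ci_low,
              100 * x$ci_high, x$n_draws, x$n_truncated))
  invisible(x)
}
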