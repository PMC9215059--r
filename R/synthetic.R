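#' Configuration for the synthetic-data generator
#'
#' Describes a fully-known ground truth from which survey-like prevalence
#' tables, relative-risk tables and annual cost series can be generated, so
#' every downstream stage of the attribution pipeline is testable without
#' external data. The generator emulates (i) a categorical BMI prevalence
#' survey with binomial sampling noise at a stated effective sample size,
#' (ii) published dose-response RRs with 95% CIs, and (iii) cost registries
#' whose annual totals follow a linear trend with additive Gaussian noise.
#'
#' @param seed integer seed fixing every generated artifact.
#' @param strata character vector of stratum labels (default `c("F", "M")`).
#' @param schema a [bmi_schema()].
#' @param true_proportions named list (by stratum) of per-category proportion
#'   vectors, each summing to 1 within 1e-9.
#' @param effective_n named vector/list (by stratum) of positive effective
#'   sample sizes (default 30,000 each, the order of a national health
#'   survey's per-sex public-system subsample).
#' @param rr_table an [rr_table()] of true dose-response RRs.
#' @param cost_trend data frame with columns `cancer`, `sex`, `intercept`,
#'   `slope`, `sd` (currency units; `sd >= 0`) describing each cost series.
#' @param years inclusive year range of the cost series (default 2008:2019).
#' @return A list of class `"synthetic_config"`.
#' @examples
#' cfg <- synthetic_config(seed = 7)
#' generate_prevalence(cfg)
#' @export
synthetic_config <- function(seed = 1L,
                             strata = c("F", "M"),
                             schema = bmi_schema(),
                             true_proportions = NULL,
                             effective_n = NULL,
                             rr_table = NULL,
                             cost_trend = NULL,
                             years = 2008:2019) {
  assert_schema(schema)
  k <- nrow(schema)
  if (is.null(true_proportions)) {
    # default truth: typical adult BMI distribution of a middle-income country
    default_p <- list(c(0.42, 0.34, 0.16, 0.08), c(0.44, 0.36, 0.14, 0.06))
    true_proportions <- stats::setNames(rep(default_p, length.out = length(strata)),
                                        strata)
  }
  if (is.null(effective_n))
    effective_n <- stats::setNames(rep(30000, length(strata)), strata)
  effective_n <- unlist(effective_n)
  if (!all(strata %in% names(true_proportions)))
    stop("true_proportions must cover every stratum", call. = FALSE)
  if (!all(strata %in% names(effective_n)))
    stop("effective_n must cover every stratum", call. = FALSE)
  for (s in strata) {
    p <- true_proportions[[s]]
    if (length(p) != k) stop("true_proportions[['", s, "']] must have ",
                             k, " categories", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop("true_proportions[['", s, "']] must sum to 1", call. = FALSE)
    if (any(p < 0)) stop("proportions must be non-negative", call. = FALSE)
    if (effective_n[[s]] < 1) stop("effective_n must be >= 1", call. = FALSE)
  }
  if (is.null(rr_table))
    rr_table <- data.frame(
      cancer = rep(c("site_a", "site_b"), each = 2),
      sex = rep(c("F", "M"), 2),
      increment = 5,
      rr = c(1.50, 1.50, 1.12, 1.12),
      ci_low = c(1.42, 1.42, 1.09, 1.09),
      ci_high = c(1.59, 1.59, 1.15, 1.15),
      stringsAsFactors = FALSE)
  rr_table <- validate_rr_table(rr_table)
  if (is.null(cost_trend))
    cost_trend <- data.frame(
      cancer = rep(c("site_a", "site_b"), each = 2),
      sex = rep(c("F", "M"), 2),
      intercept = c(80, 60, 400, 30), slope = c(6, 5, 25, 2),
      sd = c(8, 6, 30, 3), stringsAsFactors = FALSE)
  if (any(cost_trend$sd < 0)) stop("noise sd must be >= 0", call. = FALSE)
  if (length(unique(years)) < 2) stop("years must span >= 2 years", call. = FALSE)
  structure(list(seed = as.integer(seed), strata = strata, schema = schema,
                 true_proportions = true_proportions,
                 effective_n = effective_n, rr_table = rr_table,
                 cost_trend = cost_trend, years = sort(unique(years))),
            class = "synthetic_config")
}

#' Generate a survey-like prevalence table
#'
#' Draws, per stratum, category counts from a multinomial over the true
#' proportions at the stratum's effective sample size (so counts exactly
#' partition `effective_n` and observed proportions sum to 1), and attaches
#' per-category 95% Wald binomial confidence intervals clipped to `[0, 1]`.
#'
#' @param config a [synthetic_config()].
#' @param year reference year recorded on the table (default 2019).
#' @return A [prevalence_table()] with one row per stratum x category.
#' @export
generate_prevalence <- function(config, year = 2019) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- nrow(config$schema)
  rows <- lapply(config$strata, function(s) {
    n_eff <- config$effective_n[[s]]
    counts <- stats::rmultinom(1, size = n_eff, prob = config$true_proportions[[s]])[, 1]
    phat <- counts / n_eff
    se <- sqrt(phat * (1 - phat) / n_eff)
    data.frame(stratum = s, category = config$schema$label, proportion = phat,
               effective_n = n_eff, year = year,
               ci_low = pmax(phat - Z975 * se, 0),
               ci_high = pmin(phat + Z975 * se, 1),
               stringsAsFactors = FALSE)
  })
  validate_prevalence(do.call(rbind, rows))
}

#' Generate annual cost series with a known linear trend
#'
#' For each (cancer, sex) in the config's `cost_trend`,
#' `cost(year) = intercept + slope * (year - first_year) + Normal(0, sd)`,
#' floored at 0.
#'
#' @param config a [synthetic_config()].
#' @return A [cost_series()] with one row per cancer x sex x year.
#' @export
generate_cost_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  yrs <- config$years
  y0 <- min(yrs)
  rows <- lapply(seq_len(nrow(config$cost_trend)), function(i) {
    tr <- config$cost_trend[i, ]
    mu <- tr$intercept + tr$slope * (yrs - y0)
    eps <- if (tr$sd > 0) stats::rnorm(length(yrs), 0, tr$sd) else 0
    data.frame(cancer = tr$cancer, sex = tr$sex, year = yrs,
               cost = pmax(mu + eps, 0), currency = "BRL",
               stringsAsFactors = FALSE)
  })
  validate_cost_series(do.call(rbind, rows))
}

#' Ground-truth PIF implied by a synthetic configuration
#'
#' Evaluates the PIF deterministically on the noise-free true proportions
#' and point RRs of a synthetic configuration, for use as a parameter
#' recovery target.
#'
#' @param config a [synthetic_config()].
#' @param scenario an `ebw_scenario` (see [scenarios]).
#' @param cancer,sex identifiers present in the config's `rr_table`.
#' @return A single proportion.
#' @examples
#' cfg <- synthetic_config()
#' ground_truth_pif(cfg, scenario_tmrel(), "site_a", "F")
#' @export
ground_truth_pif <- function(config, scenario, cancer, sex) {
  stopifnot(inherits(config, "synthetic_config"))
  rr <- config$rr_table[config$rr_table$cancer == cancer &
                        config$rr_table$sex == sex, , drop = FALSE]
  if (nrow(rr) != 1L)
    stop("no unique RR for ", cancer, "/", sex, " in config", call. = FALSE)
  if (!sex %in% names(config$true_proportions))
    stop("stratum '", sex, "' not in config", call. = FALSE)
  p <- stats::setNames(config$true_proportions[[sex]], config$schema$label)
  deterministic_pif(p, scenario, validate_rr_table(rr), config$schema)
}

#' Write a synthetic dataset to disk
#'
#' Writes the generated prevalence table, RR table and cost series as CSV,
#' the configuration as YAML, and a manifest JSON recording the seed.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(prevalence = file.path(dir, "prevalence.csv"),
             rr = file.path(dir, "rr.csv"),
             costs = file.path(dir, "costs.csv"),
             config = file.path(dir, "config.yaml"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(generate_prevalence(config), paths["prevalence"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(config$rr_table), paths["rr"],
                   row.names = FALSE)
  utils::write.csv(generate_cost_series(config), paths["costs"],
                   row.names = FALSE)
  yaml::write_yaml(list(
    seed = config$seed, strata = as.list(config$strata),
    years = range(config$years),
    effective_n = as.list(config$effective_n),
    true_proportions = lapply(config$true_proportions, as.numeric),
    schema = list(labels = config$schema$label, lower = config$schema$lower,
                  upper = config$schema$upper, median = config$schema$median,
                  reference = config$schema$label[config$schema$reference])),
    paths["config"])
  jsonlite::write_json(list(seed = config$seed,
                            files = as.list(basename(paths[1:4]))),
                       paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
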