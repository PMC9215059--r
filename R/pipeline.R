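#' Attribute cancer costs to excess body weight
#'
#' End-to-end comparative risk assessment for one counterfactual scenario:
#' for every (cancer subtype, sex) pairing in the relative-risk table it
#' simulates the potential impact fraction by Monte Carlo (baseline
#' prevalence resampled binomially, log-RR resampled normally), projects the
#' matching annual cost series to the cost year by linear regression with
#' PPP conversion (or uses supplied pre-projected costs), and multiplies
#' PIF by cost. Subtypes listed in `site_map` are additionally re-expressed
#' at the topographic-site level (attributable cost over total site cost).
#' An exposure-outcome lag is enforced between the prevalence year and the
#' cost year.
#'
#' @param prevalence a [prevalence_table()] with one stratum per sex and
#'   `effective_n` set.
#' @param rr an [rr_table()] of dose-response RRs on their published
#'   increment (one row per cancer subtype and sex).
#' @param costs either a [cost_series()] (projected to `cost_year` and
#'   divided by `ppp`) or a data frame with columns `cancer`, `sex`, `cost`
#'   (and optionally `cost_low`, `cost_high`) already in the target
#'   currency.
#' @param schema a [bmi_schema()].
#' @param scenario an `ebw_scenario`; default [scenario_tmrel()], under
#'   which the PIF is the population attributable fraction.
#' @param mc an [mc_config()]. When `mc$seed` is set the whole run is
#'   reproducible.
#' @param ppp PPP conversion factor applied to projected cost series
#'   (default 2.281 R$ per US$; ignored for pre-projected costs).
#' @param prevalence_year,cost_year years the exposure and cost refer to
#'   (defaults 2019 and 2030).
#' @param lag minimum years between exposure and outcome (default 10).
#' @param allow_lag_violation set `TRUE` to override the lag check.
#' @param site_map optional data frame with columns `cancer` (subtype
#'   identifier in `rr`) and `site` (identifier keying the site's total cost
#'   in `costs`) for site-level reporting.
#' @return An object of class `"ebw_attribution"`: a list with `results`
#'   (one row per cancer x sex: PIF point and 95% UI, cost, attributable
#'   cost with UI), `totals` (per sex and combined), the scenario, the
#'   baseline, and run metadata. Methods: `print`, `summary`, `coef`
#'   (named PIF vector), `plot` (baseline vs counterfactual distribution).
#' @examples
#' cfg <- synthetic_config(seed = 42)
#' prev <- generate_prevalence(cfg)
#' costs <- generate_cost_series(cfg)
#' fit <- ebw_attribution(prev, cfg$rr_table, costs,
#'                        mc = mc_config(n_iterations = 500, seed = 1))
#' fit
#' @export
ebw_attribution <- function(prevalence, rr, costs, schema = bmi_schema(),
                            scenario = scenario_tmrel(), mc = mc_config(),
                            ppp = 2.281, prevalence_year = 2019,
                            cost_year = 2030, lag = 10,
                            allow_lag_violation = FALSE, site_map = NULL) {
  assert_schema(schema)
  prevalence <- validate_prevalence(prevalence)
  rr <- validate_rr_table(rr)
  if (cost_year - prevalence_year < lag && !allow_lag_violation)
    stop("cost_year - prevalence_year must be >= the exposure-outcome lag (",
         lag, " years); pass allow_lag_violation = TRUE to override",
         call. = FALSE)
  if (!is.null(mc$seed)) set.seed(mc$seed)
  mc_run <- mc; mc_run$seed <- NULL

  cost_tab <- resolve_costs(costs, cost_year, ppp)
  res <- vector("list", nrow(rr))
  for (i in seq_len(nrow(rr))) {
    row <- rr[i, , drop = FALSE]
    base_i <- prevalence[prevalence$stratum == row$sex, , drop = FALSE]
    if (nrow(base_i) == 0L)
      stop("no prevalence stratum for sex '", row$sex, "' (needed by ",
           row$cancer, ")", call. = FALSE)
    pe <- simulate_pif(base_i, scenario, row, schema, mc_run)
    cost_i <- lookup_cost(cost_tab, row$cancer, row$sex)
    att <- attributable_cost(pe, cost_i)
    res[[i]] <- data.frame(
      cancer = row$cancer, sex = row$sex, level = "subtype",
      pif = pe$point, pif_low = pe$ci_low, pif_high = pe$ci_high,
      cost = cost_i,
      attributable = att$attributable[["point"]],
      attributable_low = att$attributable[["ci_low"]],
      attributable_high = att$attributable[["ci_high"]],
      n_truncated = pe$n_truncated, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)

  if (!is.null(site_map)) {
    for (j in seq_len(nrow(site_map))) {
      sub <- site_map$cancer[j]; site <- site_map$site[j]
      idx <- which(results$cancer == sub)
      for (i in idx) {
        sex_i <- results$sex[i]
        site_cost <- lookup_cost(cost_tab, site, sex_i)
        results$cancer[i] <- site
        results$level[i] <- "site"
        results$pif[i] <- pif_site(results$attributable[i], site_cost)
        results$pif_low[i] <- pif_site(results$attributable_low[i], site_cost)
        results$pif_high[i] <- pif_site(
          min(results$attributable_high[i], site_cost), site_cost)
        results$cost[i] <- site_cost
      }
    }
  }

  totals <- attribution_totals(results)
  structure(list(results = results, totals = totals, scenario = scenario,
                 schema = schema, baseline = prevalence, mc = mc,
                 prevalence_year = prevalence_year, cost_year = cost_year,
                 ppp = ppp, call = match.call()),
            class = "ebw_attribution")
}

# costs -> data.frame(cancer, sex, cost) in target currency at cost_year
resolve_costs <- function(costs, cost_year, ppp) {
  if (inherits(costs, "cost_series") ||
      all(c("year", "cost") %in% names(costs))) {
    costs <- validate_cost_series(costs)
    keys <- unique(costs[c("cancer", "sex")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
      s <- costs[costs$cancer == keys$cancer[i] & costs$sex == keys$sex[i], ,
                 drop = FALSE]
      pr <- fit_and_project(s, cost_year)
      data.frame(cancer = keys$cancer[i], sex = keys$sex[i],
                 cost = ppp_convert(pr$point, ppp),
                 cost_low = ppp_convert(pr$low, ppp),
                 cost_high = ppp_convert(pr$high, ppp),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    if (!all(c("cancer", "sex", "cost") %in% names(costs)))
      stop("costs must be a cost_series or have columns cancer, sex, cost",
           call. = FALSE)
    costs
  }
}

lookup_cost <- function(cost_tab, cancer, sex) {
  hit <- cost_tab$cost[cost_tab$cancer == cancer & cost_tab$sex == sex]
  if (length(hit) != 1L)
    stop("no unique cost for ", cancer, "/", sex, call. = FALSE)
  hit
}

attribution_totals <- function(results) {
  agg <- function(rows, sex_label) {
    data.frame(sex = sex_label,
               cost = sum(rows$cost),
               attributable = sum(rows$attributable),
               attributable_low = sum(rows$attributable_low),
               attributable_high = sum(rows$attributable_high),
               pif = sum(rows$attributable) / sum(rows$cost),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(results, results$sex),
                               function(r) agg(r, r$sex[1])))
  rbind(out, agg(results, "T"))
}

#' Potential savings under counterfactual BMI scenarios
#'
#' For each scenario, computes the reduction in projected future cancer
#' costs achievable if the BMI distribution reached the scenario's levels at
#' an intermediate year: savings = PIF(scenario) x projected cost, per
#' cancer and sex, with Monte Carlo uncertainty. The baseline distribution
#' for the intermediate year may be supplied directly or projected from two
#' observed surveys with [project_prevalence()].
#'
#' @param baseline a [prevalence_table()] for the intermediate year (e.g. a
#'   projected 2030 distribution), with `effective_n`.
#' @param rr,costs,schema,mc,ppp,site_map as in [ebw_attribution()].
#' @param scenarios named list of `ebw_scenario` objects.
#' @param prevalence_year,cost_year exposure and cost years (defaults 2030
#'   and 2040); the 10-year lag is enforced as in [ebw_attribution()].
#' @param lag,allow_lag_violation as in [ebw_attribution()].
#' @return An object of class `"ebw_savings"`: `results` has one row per
#'   cancer x sex x scenario with PIF and savings (point, 95% UI); `totals`
#'   aggregates per sex and scenario.
#' @export
ebw_savings <- function(baseline, rr, costs, scenarios,
                        schema = bmi_schema(), mc = mc_config(), ppp = 2.281,
                        prevalence_year = 2030, cost_year = 2040, lag = 10,
                        allow_lag_violation = FALSE, site_map = NULL) {
  if (!is.list(scenarios) || !all(vapply(scenarios, inherits, TRUE, "ebw_scenario")))
    stop("scenarios must be a list of ebw_scenario objects", call. = FALSE)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  fits <- lapply(names(scenarios), function(nm) {
    fit <- ebw_attribution(baseline, rr, costs, schema = schema,
                           scenario = scenarios[[nm]], mc = mc, ppp = ppp,
                           prevalence_year = prevalence_year,
                           cost_year = cost_year, lag = lag,
                           allow_lag_violation = allow_lag_violation,
                           site_map = site_map)
    r <- fit$results
    r$scenario <- nm
    names(r)[names(r) == "attributable"] <- "savings"
    names(r)[names(r) == "attributable_low"] <- "savings_low"
    names(r)[names(r) == "attributable_high"] <- "savings_high"
    t <- fit$totals
    t$scenario <- nm
    list(results = r, totals = t)
  })
  results <- do.call(rbind, lapply(fits, `[[`, "results"))
  totals <- do.call(rbind, lapply(fits, `[[`, "totals"))
  names(totals)[names(totals) == "attributable"] <- "savings"
  names(totals)[names(totals) == "attributable_low"] <- "savings_low"
  names(totals)[names(totals) == "attributable_high"] <- "savings_high"
  rownames(results) <- rownames(totals) <- NULL
  structure(list(results = results, totals = totals, scenarios = scenarios,
                 schema = schema, baseline = baseline, mc = mc,
                 prevalence_year = prevalence_year, cost_year = cost_year,
                 call = match.call()),
            class = "ebw_savings")
}

#' Write report files for an attribution or savings run
#'
#' Emits the result and total tables as CSV plus a manifest JSON recording
#' the seed, iteration count, scenario labels and MD5 checksums of the
#' written files, so a report can be traced back to its configuration.
#'
#' @param x an `ebw_attribution` or `ebw_savings` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(x, dir) {
  stopifnot(inherits(x, c("ebw_attribution", "ebw_savings")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kind <- if (inherits(x, "ebw_attribution")) "attribution" else "savings"
  paths <- c(results = file.path(dir, paste0(kind, "_results.csv")),
             totals = file.path(dir, paste0(kind, "_totals.csv")))
  utils::write.csv(x$results, paths["results"], row.names = FALSE)
  utils::write.csv(x$totals, paths["totals"], row.names = FALSE)
  manifest <- list(
    kind = kind,
    seed = x$mc$seed, n_iterations = x$mc$n_iterations,
    truncate_negative = x$mc$truncate_negative,
    prevalence_year = x$prevalence_year, cost_year = x$cost_year,
    scenario = if (kind == "attribution") x$scenario$label
               else lapply(x$scenarios, `[[`, "label"),
    checksums = as.list(tools::md5sum(unname(paths))))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = mpath))
}
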