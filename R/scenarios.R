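#' Counterfactual BMI-distribution scenarios
#'
#' Constructors for the counterfactual scenarios contrasted against the
#' baseline BMI distribution when computing potential impact fractions:
#'
#' * `scenario_tmrel()` — theoretical minimum risk exposure level: the whole
#'   population in the reference category (BMI < 25 kg/m^2). The PIF under
#'   this scenario is the population attributable fraction (PAF).
#' * `scenario_target(table)` — an externally supplied target distribution,
#'   e.g. rolling BMI back to an earlier survey's levels.
#' * `scenario_hold(table = NULL)` — halt the rise in excess body weight:
#'   the counterfactual is a designated reference-year distribution (when
#'   `table` is `NULL`, the baseline itself, giving PIF = 0).
#' * `scenario_truncate(threshold, reallocate_to)` — eliminate the categories
#'   at or above `threshold` kg/m^2 (default 35, obesity classes II-III),
#'   moving their mass to the adjacent remaining category (default) or to
#'   the reference category.
#' * `scenario_mean_shift(shift, eligible_min)` — reduce the BMI of everyone
#'   at or above `eligible_min` (default 25) by `shift` kg/m^2 (default 1).
#'   Prevalences are unchanged; the shift is realised by lowering the
#'   category medians used for the counterfactual relative risks (see
#'   [shift_schema_medians()]).
#'
#' @param table a [prevalence_table()] (target or reference-year distribution).
#' @param threshold BMI bound (kg/m^2) above which categories are eliminated.
#' @param reallocate_to `"below"` (adjacent category under the threshold) or
#'   `"reference"`.
#' @param shift,eligible_min mean-shift magnitude and eligibility bound, kg/m^2.
#' @return An object of class `"ebw_scenario"`.
#' @name scenarios
NULL

new_scenario <- function(kind, label, ...) {
  structure(list(kind = kind, label = label, ...), class = "ebw_scenario")
}

#' @rdname scenarios
#' @export
scenario_tmrel <- function() new_scenario("tmrel", "all-reference (PAF)")

#' @rdname scenarios
#' @export
scenario_target <- function(table) {
  if (missing(table) || !inherits(table, "prevalence_table"))
    stop("scenario_target requires a prevalence_table", call. = FALSE)
  new_scenario("target", "target distribution", table = table)
}

#' @rdname scenarios
#' @export
scenario_hold <- function(table = NULL) {
  if (!is.null(table) && !inherits(table, "prevalence_table"))
    stop("table must be a prevalence_table or NULL", call. = FALSE)
  new_scenario("hold", "hold at reference year", table = table)
}

#' @rdname scenarios
#' @export
scenario_truncate <- function(threshold = 35, reallocate_to = c("below", "reference")) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  new_scenario("truncate", sprintf("eliminate BMI >= %g", threshold),
               threshold = threshold, reallocate_to = match.arg(reallocate_to))
}

#' @rdname scenarios
#' @export
scenario_mean_shift <- function(shift = 1, eligible_min = 25) {
  if (shift <= 0) stop("shift must be positive", call. = FALSE)
  new_scenario("mean_shift", sprintf("-%g kg/m^2 mean shift", shift),
               shift = shift, eligible_min = eligible_min)
}

#' @export
print.ebw_scenario <- function(x, ...) {
  cat("Counterfactual scenario:", x$label, "\n")
  invisible(x)
}

#' Apply a counterfactual scenario to a baseline distribution
#'
#' Produces the counterfactual prevalence table (and, for the mean-shift
#' scenario, the schema with shifted medians to be used when computing the
#' counterfactual relative risks). Outputs always satisfy the simplex
#' constraint: proportions per stratum sum to 1.
#'
#' @param baseline a [prevalence_table()].
#' @param spec an `ebw_scenario` (see [scenarios]).
#' @param schema the [bmi_schema()] shared by baseline and scenario.
#' @return A list with elements `prevalence` (counterfactual
#'   `prevalence_table`), `schema` (the schema to use for counterfactual
#'   RRs; differs from the input only for the mean-shift scenario) and
#'   `noop` (`TRUE` if the scenario had nothing to change, with a warning).
#' @examples
#' b <- prevalence_table(rep("F", 4), c("<25", "25-30", "30-35", ">=35"),
#'                       c(0.40, 0.30, 0.20, 0.10))
#' apply_scenario(b, scenario_truncate(35), bmi_schema())$prevalence
#' @export
apply_scenario <- function(baseline, spec, schema) {
  if (!inherits(spec, "ebw_scenario")) stop("spec must be an ebw_scenario", call. = FALSE)
  assert_schema(schema)
  baseline <- validate_prevalence(baseline)
  noop <- FALSE
  cf_schema <- schema
  cf <- switch(spec$kind,
    tmrel = {
      out <- baseline
      ref <- schema$label[schema$reference]
      out$proportion <- ifelse(out$category == ref, 1, 0)
      out
    },
    target = {
      check_same_layout(baseline, spec$table)
      spec$table
    },
    hold = {
      if (is.null(spec$table)) baseline else {
        check_same_layout(baseline, spec$table)
        spec$table
      }
    },
    truncate = {
      elim <- schema$label[schema$lower >= spec$threshold]
      keep <- schema$label[schema$lower < spec$threshold]
      if (length(keep) == 0L)
        stop("threshold excludes every category", call. = FALSE)
      dest <- if (spec$reallocate_to == "reference")
        schema$label[schema$reference] else keep[length(keep)]
      out <- baseline
      if (length(elim) == 0L) {
        noop <- TRUE
        warning("no category at or above the threshold; baseline unchanged")
      } else {
        for (s in unique(out$stratum)) {
          idx <- out$stratum == s
          moved <- sum(out$proportion[idx & out$category %in% elim])
          out$proportion[idx & out$category %in% elim] <- 0
          di <- idx & out$category == dest
          out$proportion[di] <- out$proportion[di] + moved
        }
      }
      out
    },
    mean_shift = {
      cf_schema <- shift_schema_medians(schema, spec$shift, spec$eligible_min)
      baseline
    },
    stop("unknown scenario kind: ", spec$kind, call. = FALSE))
  cf$ci_low <- NA_real_; cf$ci_high <- NA_real_
  list(prevalence = validate_prevalence(cf), schema = cf_schema, noop = noop)
}

check_same_layout <- function(a, b) {
  ka <- paste(a$stratum, a$category, sep = "\r")
  kb <- paste(b$stratum, b$category, sep = "\r")
  if (!setequal(ka, kb))
    stop("baseline and counterfactual tables must share strata and categories",
         call. = FALSE)
  invisible(TRUE)
}
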