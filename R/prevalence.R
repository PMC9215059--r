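#' Prevalence table of BMI categories by stratum
#'
#' A long-format table of per-category population proportions by stratum
#' (typically sex). Proportions within each stratum must sum to 1.
#'
#' @param stratum character stratum identifier (e.g. `"F"`, `"M"`).
#' @param category character category label, matching a [bmi_schema()].
#' @param proportion numeric proportions in `[0, 1]`.
#' @param effective_n optional effective sample size per stratum (used by the
#'   Monte Carlo binomial resampling); may be `NA`.
#' @param year optional reference year of the survey.
#' @param ci_low,ci_high optional per-category confidence bounds.
#' @return A data frame of class `"prevalence_table"`.
#' @examples
#' prevalence_table(
#'   stratum = rep("F", 4),
#'   category = c("<25", "25-30", "30-35", ">=35"),
#'   proportion = c(0.45, 0.30, 0.17, 0.08),
#'   effective_n = 30000, year = 2019)
#' @export
prevalence_table <- function(stratum, category, proportion,
                             effective_n = NA_real_, year = NA_integer_,
                             ci_low = NA_real_, ci_high = NA_real_) {
  out <- data.frame(stratum = as.character(stratum),
                    category = as.character(category),
                    proportion = as.numeric(proportion),
                    effective_n = effective_n, year = year,
                    ci_low = ci_low, ci_high = ci_high,
                    stringsAsFactors = FALSE)
  validate_prevalence(out)
}

validate_prevalence <- function(x, tol = 1e-9) {
  if (any(x$proportion < -tol | x$proportion > 1 + tol))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  sums <- tapply(x$proportion, x$stratum, sum)
  if (any(abs(sums - 1) > tol))
    stop("proportions must sum to 1 within each stratum (worst deviation ",
         format(max(abs(sums - 1))), ")", call. = FALSE)
  if (any(duplicated(x[c("stratum", "category")])))
    stop("duplicated stratum/category rows", call. = FALSE)
  class(x) <- unique(c("prevalence_table", class(x)))
  x
}

#' Extract one stratum's proportions as a named vector ordered by schema
#' @noRd
stratum_proportions <- function(table, stratum, schema) {
  assert_schema(schema)
  rows <- table[table$stratum == stratum, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("stratum '", stratum, "' not found in prevalence table", call. = FALSE)
  m <- match(schema$label, rows$category)
  if (anyNA(m))
    stop("prevalence table for stratum '", stratum,
         "' does not cover schema categories: ",
         paste(schema$label[is.na(m)], collapse = ", "), call. = FALSE)
  p <- rows$proportion[m]
  names(p) <- schema$label
  p
}

#' Project a baseline prevalence distribution to a future year
#'
#' Linear per-category extrapolation between two observed surveys, clipped to
#' `[0, 1]` and renormalised to sum to 1 within each stratum. Used to obtain
#' a future-year baseline BMI distribution when the savings analysis needs
#' one (e.g. a 2030 baseline from 2013 and 2019 surveys).
#'
#' @param early,late `prevalence_table`s for the same strata and categories,
#'   with `year` set; `early` must predate `late`.
#' @param target_year year to extrapolate to (`>= late` year).
#' @return A `prevalence_table` for `target_year`.
#' @examples
#' e <- prevalence_table(c("F", "F"), c("<25", ">=25"), c(0.5, 0.5), year = 2008)
#' l <- prevalence_table(c("F", "F"), c("<25", ">=25"), c(0.4, 0.6), year = 2019)
#' project_prevalence(e, l, 2030)
#' @export
project_prevalence <- function(early, late, target_year) {
  y0 <- unique(early$year); y1 <- unique(late$year)
  if (length(y0) != 1L || length(y1) != 1L || is.na(y0) || is.na(y1))
    stop("each table must carry a single non-missing year", call. = FALSE)
  if (!(y0 < y1 && y1 <= target_year))
    stop("need early year < late year <= target year", call. = FALSE)
  key_e <- paste(early$stratum, early$category, sep = "\r")
  key_l <- paste(late$stratum, late$category, sep = "\r")
  if (nrow(early) != nrow(late) || !setequal(key_e, key_l))
    stop("early and late tables must share strata and categories", call. = FALSE)
  ord <- match(key_l, key_e)
  slope <- (late$proportion - early$proportion[ord]) / (y1 - y0)
  p <- late$proportion + slope * (target_year - y1)
  p <- pmin(pmax(p, 0), 1)
  out <- late
  out$proportion <- p
  for (s in unique(out$stratum)) {
    idx <- out$stratum == s
    tot <- sum(out$proportion[idx])
    if (tot <= 0) stop("projection degenerated to zero mass in stratum ", s,
                       call. = FALSE)
    out$proportion[idx] <- out$proportion[idx] / tot
  }
  out$year <- target_year
  out$ci_low <- NA_real_; out$ci_high <- NA_real_
  validate_prevalence(out)
}
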