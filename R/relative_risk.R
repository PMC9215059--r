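#' Relative-risk table per BMI increment
#'
#' Holds dose-response relative risks per `increment` kg/m^2 of BMI with 95%
#' confidence bounds, one row per cancer subtype and sex. This is the form
#' in which meta-analytic summary RRs are published (usually per 5 kg/m^2).
#'
#' @param cancer character cancer subtype identifier.
#' @param sex character sex code (`"F"`/`"M"`).
#' @param increment BMI increment (kg/m^2) the RR refers to; positive.
#' @param rr,ci_low,ci_high relative risk point estimate and 95% CI bounds;
#'   all positive, `ci_low <= rr <= ci_high`.
#' @return A data frame of class `"rr_table"`.
#' @examples
#' rr_table("endometrium", "F", 5, 1.50, 1.42, 1.59)
#' @export
rr_table <- function(cancer, sex, increment, rr, ci_low, ci_high) {
  out <- data.frame(cancer = as.character(cancer), sex = as.character(sex),
                    increment = as.numeric(increment), rr = as.numeric(rr),
                    ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
                    stringsAsFactors = FALSE)
  validate_rr_table(out)
}

validate_rr_table <- function(x) {
  if (any(x$increment <= 0)) stop("increment must be positive", call. = FALSE)
  if (any(c(x$rr, x$ci_low, x$ci_high) <= 0))
    stop("relative risks and CI bounds must be positive", call. = FALSE)
  if (any(x$ci_low > x$rr | x$rr > x$ci_high))
    stop("need ci_low <= rr <= ci_high", call. = FALSE)
  class(x) <- unique(c("rr_table", class(x)))
  x
}

#' Rescale relative risks to a different BMI increment
#'
#' Converts a relative risk per `x` kg/m^2 to a relative risk per
#' `target_increment` kg/m^2 under the log-linear dose-response model:
#' `RR_target = exp(log(RR_x) * target / x)`, i.e. for a 1-unit target,
#' `RR_1 = exp(log(RR_x) / x)`. CI bounds are transformed by the same power,
#' which is the transform implied by rescaling the log-scale interval.
#'
#' @param table an [rr_table()] (one or more rows).
#' @param target_increment target BMI increment in kg/m^2 (default 1).
#' @return An `rr_table` expressed per `target_increment`.
#' @examples
#' t1 <- rr_table("endometrium", "F", 5, 1.50, 1.42, 1.59)
#' rescale_rr(t1, 1)  # rr = 1.50^(1/5) = 1.0845...
#' @export
rescale_rr <- function(table, target_increment = 1) {
  table <- validate_rr_table(table)
  if (length(target_increment) != 1 || target_increment <= 0)
    stop("target_increment must be a single positive number", call. = FALSE)
  pow <- target_increment / table$increment
  out <- table
  out$rr <- table$rr^pow
  out$ci_low <- table$ci_low^pow
  out$ci_high <- table$ci_high^pow
  out$increment <- target_increment
  out
}

#' Expand a per-unit relative risk over BMI categories
#'
#' Computes the categorical relative risk profile
#' `RR_c = RR_1 ^ (M_c - M_ref)` for every category `c` of a BMI schema,
#' where `M_c` is the category median and `M_ref` the median of the
#' reference category. The reference category has `RR = 1` exactly.
#'
#' @param table an [rr_table()] expressed per 1 kg/m^2 (see [rescale_rr()]).
#' @param schema a [bmi_schema()].
#' @return A data frame of class `"rr_profile"` with one row per
#'   cancer x sex x category and columns `cancer`, `sex`, `category`, `rr`
#'   (plus `ci_low`/`ci_high` transformed by the same exponent).
#' @examples
#' t1 <- rescale_rr(rr_table("endometrium", "F", 5, 1.50, 1.42, 1.59))
#' categorical_profile(t1, bmi_schema())
#' @export
categorical_profile <- function(table, schema) {
  table <- validate_rr_table(table)
  assert_schema(schema)
  if (any(abs(table$increment - 1) > 1e-12))
    stop("categorical_profile expects RRs per 1 kg/m^2; call rescale_rr first",
         call. = FALSE)
  expo <- schema$median - reference_median(schema)
  n <- nrow(table); k <- nrow(schema)
  out <- data.frame(
    cancer = rep(table$cancer, each = k),
    sex = rep(table$sex, each = k),
    category = rep(schema$label, times = n),
    rr = as.vector(t(outer(table$rr, expo, `^`))),
    ci_low = as.vector(t(outer(table$ci_low, expo, `^`))),
    ci_high = as.vector(t(outer(table$ci_high, expo, `^`))),
    stringsAsFactors = FALSE)
  # a CI bound below 1 flips sides under a negative exponent; reorder
  swap <- out$ci_low > out$ci_high
  tmp <- out$ci_low[swap]; out$ci_low[swap] <- out$ci_high[swap]
  out$ci_high[swap] <- tmp
  class(out) <- c("rr_profile", "data.frame")
  out
}

profile_vector <- function(profile, cancer, sex, schema) {
  rows <- profile[profile$cancer == cancer & profile$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no RR profile for ", cancer, "/", sex, call. = FALSE)
  m <- match(schema$label, rows$category)
  if (anyNA(m)) stop("RR profile does not cover schema categories", call. = FALSE)
  rr <- rows$rr[m]
  names(rr) <- schema$label
  rr
}

#' Pool per-study estimates by random-effects meta-analysis
#'
#' DerSimonian-Laird random-effects pooling of per-study log relative risks,
#' with optional filtering by outcome type (used to re-pool published
#' meta-analyses on incidence studies only). Delegates the fit to
#' [metafor::rma()] with `method = "DL"`.
#'
#' @param studies data frame with columns `study`, `log_rr`, `se` (log-scale
#'   standard error, positive) and optionally `outcome`
#'   (`"incidence"`/`"mortality"`).
#' @param outcome_filter if non-`NULL`, keep only studies with this outcome.
#' @param increment BMI increment the study effects refer to (metadata
#'   carried onto the pooled estimate; default 5 kg/m^2).
#' @param cancer,sex identifiers for the pooled estimate.
#' @return A one-row [rr_table()] with the pooled RR and 95% CI, plus
#'   attributes `tau2` (between-study variance) and `k` (number of studies).
#' @examples
#' s <- data.frame(study = c("a", "b", "c"),
#'                 log_rr = c(0.10, 0.20, 0.00),
#'                 se = c(0.05, 0.10, 0.08),
#'                 outcome = "incidence")
#' pool_random_effects(s)
#' @export
pool_random_effects <- function(studies, outcome_filter = NULL, increment = 5,
                                cancer = "pooled", sex = "both") {
  req <- c("study", "log_rr", "se")
  if (!all(req %in% names(studies)))
    stop("studies must have columns study, log_rr, se", call. = FALSE)
  if (!is.null(outcome_filter)) {
    if (!"outcome" %in% names(studies))
      stop("outcome_filter given but studies has no outcome column", call. = FALSE)
    studies <- studies[studies$outcome == outcome_filter, , drop = FALSE]
  }
  if (nrow(studies) == 0L)
    stop("no studies left after filtering", call. = FALSE)
  if (any(studies$se <= 0)) stop("standard errors must be positive", call. = FALSE)
  fit <- metafor::rma(yi = studies$log_rr, sei = studies$se, method = "DL")
  out <- rr_table(cancer, sex, increment,
                  rr = exp(as.numeric(fit$beta)),
                  ci_low = exp(fit$ci.lb), ci_high = exp(fit$ci.ub))
  attr(out, "tau2") <- fit$tau2
  attr(out, "k") <- fit$k
  out
}
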