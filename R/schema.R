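#' BMI category schema
#'
#' Defines the ordered BMI strata over which prevalences and categorical
#' relative risks are expressed. Each category is a half-open interval
#' `[lower, upper)` in kg/m^2 with a representative median used as the
#' exposure value in the log-linear risk model. Exactly one category is the
#' reference (the theoretical minimum risk exposure level, conventionally
#' BMI < 25 kg/m^2).
#'
#' @param labels character vector of category labels, in increasing BMI order.
#' @param lower,upper numeric interval bounds in kg/m^2; intervals must be
#'   ordered and non-overlapping (`upper[i] == lower[i + 1]`).
#' @param median numeric representative median BMI of each category
#'   (`lower <= median < upper`).
#' @param reference label of the reference category.
#' @return A data frame of class `"bmi_schema"` with columns `label`, `lower`,
#'   `upper`, `median`, `reference`.
#' @examples
#' bmi_schema()  # default: <25 (ref), 25-<30, 30-<35, >=35
#' @export
bmi_schema <- function(labels = c("<25", "25-30", "30-35", ">=35"),
                       lower = c(0, 25, 30, 35),
                       upper = c(25, 30, 35, Inf),
                       median = c(22, 27, 32, 37),
                       reference = labels[1]) {
  n <- length(labels)
  if (length(lower) != n || length(upper) != n || length(median) != n)
    stop("labels, lower, upper and median must have equal length", call. = FALSE)
  if (anyDuplicated(labels))
    stop("category labels must be unique", call. = FALSE)
  if (any(lower >= upper))
    stop("each category needs lower < upper", call. = FALSE)
  if (n > 1 && any(abs(upper[-n] - lower[-1]) > 1e-9))
    stop("categories must be contiguous and ordered by BMI", call. = FALSE)
  if (any(median < lower | median >= upper))
    stop("category medians must satisfy lower <= median < upper", call. = FALSE)
  if (length(reference) != 1 || !reference %in% labels)
    stop("reference must name exactly one category", call. = FALSE)
  out <- data.frame(label = as.character(labels), lower = lower, upper = upper,
                    median = median, reference = labels == reference,
                    stringsAsFactors = FALSE)
  class(out) <- c("bmi_schema", "data.frame")
  out
}

#' @export
print.bmi_schema <- function(x, ...) {
  cat("BMI category schema (kg/m^2):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

is_bmi_schema <- function(x) inherits(x, "bmi_schema")

assert_schema <- function(schema) {
  if (!is_bmi_schema(schema)) stop("not a bmi_schema object", call. = FALSE)
  if (sum(schema$reference) != 1L)
    stop("schema must have exactly one reference category", call. = FALSE)
  invisible(schema)
}

reference_median <- function(schema) {
  assert_schema(schema)
  schema$median[schema$reference]
}

#' Shift category medians for exposed categories
#'
#' Returns a copy of the schema whose medians have been lowered by `shift`
#' kg/m^2 for every category whose lower bound is at or above
#' `eligible_min`. This realises a population mean-shift counterfactual at
#' the category level: under the log-linear model, lowering every exposed
#' person's BMI by `shift` is equivalent to lowering the category medians
#' used to compute categorical relative risks.
#'
#' @param schema a [bmi_schema()].
#' @param shift reduction in kg/m^2 (positive).
#' @param eligible_min BMI threshold defining the exposed categories
#'   (default 25, i.e. excess body weight).
#' @return A `bmi_schema` with shifted medians. Bounds are left untouched;
#'   the shifted median may fall below the category lower bound by design.
#' @export
shift_schema_medians <- function(schema, shift = 1, eligible_min = 25) {
  assert_schema(schema)
  if (shift < 0) stop("shift must be non-negative", call. = FALSE)
  out <- schema
  idx <- out$lower >= eligible_min
  out$median[idx] <- out$median[idx] - shift
  out
}
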