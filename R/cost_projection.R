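#' Annual cost series
#'
#' Long-format annual direct healthcare cost series per cancer type and sex.
#'
#' @param cancer,sex identifiers.
#' @param year integer calendar years (>= 2 distinct per series).
#' @param cost non-negative annual costs.
#' @param currency currency tag (default `"BRL"`).
#' @return A data frame of class `"cost_series"`.
#' @export
cost_series <- function(cancer, sex, year, cost, currency = "BRL") {
  out <- data.frame(cancer = as.character(cancer), sex = as.character(sex),
                    year = as.integer(year), cost = as.numeric(cost),
                    currency = currency, stringsAsFactors = FALSE)
  validate_cost_series(out)
}

validate_cost_series <- function(x) {
  if (any(x$cost < 0)) stop("costs must be non-negative", call. = FALSE)
  n_years <- tapply(x$year, paste(x$cancer, x$sex), function(y) length(unique(y)))
  if (any(n_years < 2))
    stop("each series needs at least 2 distinct years", call. = FALSE)
  class(x) <- unique(c("cost_series", class(x)))
  x
}

#' Project an annual cost series to a target year
#'
#' Ordinary least squares of cost on calendar year (year centred for
#' conditioning), evaluated at the target year with a t-distribution
#' prediction interval. A negative projection is floored at 0 with a
#' warning.
#'
#' @param series a [cost_series()] holding exactly one (cancer, sex) series.
#' @param target_year year to project to (>= last observed year).
#' @param interval_level prediction-interval coverage (default 0.95).
#' @return A list of class `"cost_projection"` with elements `cancer`, `sex`,
#'   `target_year`, `point`, `low`, `high`, `intercept`, `slope` (per year,
#'   with intercept at the first observed year), and `currency`.
#' @examples
#' s <- cost_series("kidney", "M", 2008:2019, 100 + 10 * (0:11))
#' fit_and_project(s, 2030)$point  # exactly 320
#' @export
fit_and_project <- function(series, target_year, interval_level = 0.95) {
  series <- validate_cost_series(series)
  if (length(unique(paste(series$cancer, series$sex))) != 1L)
    stop("fit_and_project expects a single (cancer, sex) series", call. = FALSE)
  if (length(unique(series$year)) < 2L)
    stop("need at least 2 distinct years", call. = FALSE)
  if (target_year < max(series$year))
    stop("target_year must not precede the last observed year", call. = FALSE)
  ybar <- mean(series$year)
  fit <- stats::lm(cost ~ I(year - ybar), data = series)
  pred <- stats::predict(fit, newdata = data.frame(year = target_year),
                         interval = "prediction", level = interval_level)
  point <- unname(pred[1, "fit"]); lo <- unname(pred[1, "lwr"]); hi <- unname(pred[1, "upr"])
  if (point < 0) {
    warning("projected cost is negative; floored at 0")
    point <- 0
  }
  lo <- max(lo, 0)
  coefs <- stats::coef(fit)
  slope <- unname(coefs[2])
  structure(list(
    cancer = series$cancer[1], sex = series$sex[1],
    target_year = target_year, point = point, low = min(lo, point),
    high = max(hi, point),
    intercept = unname(coefs[1]) - slope * (ybar - min(series$year)),
    slope = slope, currency = series$currency[1],
    level = interval_level), class = "cost_projection")
}

#' @export
print.cost_projection <- function(x, ...) {
  cat(sprintf("%s/%s %d: %.2f (%.0f%% PI %.2f-%.2f) %s\n", x$cancer, x$sex,
              x$target_year, x$point, 100 * x$level, x$low, x$high, x$currency))
  invisible(x)
}

#' Purchasing-power-parity currency conversion
#'
#' Converts local-currency amounts to international dollars by dividing by a
#' PPP conversion factor (2.281 R$ per US$ for Brazil in 2019).
#'
#' @param amount amount(s) in local currency.
#' @param factor PPP conversion factor (> 0), local units per dollar.
#' @return `amount / factor`.
#' @examples
#' ppp_convert(2.281)          # 1
#' ppp_convert(228.10, 2.281)  # 100
#' @export
ppp_convert <- function(amount, factor = 2.281) {
  if (length(factor) != 1 || !is.finite(factor) || factor <= 0)
    stop("PPP factor must be a single positive number", call. = FALSE)
  amount / factor
}
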