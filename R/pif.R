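#' Potential impact fraction for a cancer subtype
#'
#' Computes the potential impact fraction
#' \deqn{PIF = \frac{\sum_i P_i RR_i - \sum_i P'_i RR'_i}{\sum_i P_i RR_i}}
#' contrasting a baseline category distribution `p` against a counterfactual
#' `p_cf` under categorical relative risks `rr` (and optionally a separate
#' counterfactual profile `rr_cf`, used by the mean-shift scenario where the
#' distribution is unchanged but exposure values move). When the
#' counterfactual places all mass in the reference category the PIF equals
#' the population attributable fraction (PAF). Negative values (a
#' counterfactual worse than baseline) are returned as computed; truncation
#' at 0 is applied only inside Monte Carlo summaries.
#'
#' @param p,p_cf numeric baseline and counterfactual proportions over the
#'   same ordered categories; each sums to 1.
#' @param rr positive categorical relative risks, same order.
#' @param rr_cf counterfactual relative risks (defaults to `rr`).
#' @return A single proportion (can be negative; at most 1).
#' @examples
#' pif_subtype(c(0.5, 0.5), c(1, 0), c(1, 2))  # (1.5 - 1)/1.5 = 1/3
#' @export
pif_subtype <- function(p, p_cf, rr, rr_cf = rr) {
  k <- length(p)
  if (length(p_cf) != k || length(rr) != k || length(rr_cf) != k)
    stop("p, p_cf, rr (and rr_cf) must have equal length", call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(rr)) &&
      !identical(names(p), names(rr)))
    stop("category names of p and rr disagree", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(p_cf) - 1) > 1e-6)
    stop("proportions must sum to 1", call. = FALSE)
  if (any(rr <= 0) || any(rr_cf <= 0))
    stop("relative risks must be positive", call. = FALSE)
  denom <- sum(p * rr)
  if (denom <= 0) stop("baseline risk-weighted sum is zero", call. = FALSE)
  (denom - sum(p_cf * rr_cf)) / denom
}

#' Potential impact fraction at the topographic-site level
#'
#' For subtypes that cover only part of a topographic site (oesophageal
#' adenocarcinoma within oesophagus, cardia within stomach, advanced within
#' prostate, postmenopausal within breast), the site-level PIF is the
#' subtype attributable cost divided by the total cost of the site.
#'
#' @param attributable_cost cost attributable to the subtype (>= 0).
#' @param total_site_cost total cost of the topographic site (> 0,
#'   `>= attributable_cost`).
#' @return A proportion in `[0, 1]`.
#' @examples
#' pif_site(16.77, 620.39)  # 0.02703...
#' @export
pif_site <- function(attributable_cost, total_site_cost) {
  if (any(total_site_cost <= 0)) stop("total site cost must be positive", call. = FALSE)
  if (any(attributable_cost < 0)) stop("attributable cost must be >= 0", call. = FALSE)
  if (any(attributable_cost > total_site_cost + 1e-9))
    stop("attributable cost exceeds total site cost", call. = FALSE)
  attributable_cost / total_site_cost
}

#' Attributable cost from a PIF estimate and a cost
#'
#' Multiplies a PIF estimate (point and uncertainty bounds) by a fixed cost.
#' The cost is held fixed across the interval — the uncertainty propagated
#' is that of the PIF, matching an attribution where the cost projection is
#' treated as a deterministic input.
#'
#' @param pif a `pif_estimate` (see [simulate_pif()]) or a bare proportion.
#' @param cost non-negative cost (e.g. million US$ PPP).
#' @return A list of class `"attribution_result"` with elements `pif`,
#'   `cost`, and `attributable` (point, ci_low, ci_high).
#' @examples
#' attributable_cost(0.2460, 36.62)  # 9.01 to 2 dp
#' @export
attributable_cost <- function(pif, cost) {
  if (cost < 0) stop("cost must be non-negative", call. = FALSE)
  if (is.numeric(pif)) pif <- list(point = pif, ci_low = pif, ci_high = pif,
                                   n_draws = 0L)
  structure(list(
    pif = pif, cost = cost,
    attributable = c(point = pif$point * cost,
                     ci_low = pif$ci_low * cost,
                     ci_high = pif$ci_high * cost)),
    class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, digits = 2, ...) {
  a <- x$attributable
  cat(sprintf("PIF %.2f%% x cost %.2f = %.*f (%.*f-%.*f)\n",
              100 * x$pif$point, x$cost, digits, a["point"],
              digits, a["ci_low"], digits, a["ci_high"]))
  invisible(x)
}
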