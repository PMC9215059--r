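#' @export
print.ebw_attribution <- function(x, digits = 2, ...) {
  cat("Cancer costs attributable to excess body weight\n")
  cat("  scenario:       ", x$scenario$label, "\n")
  cat("  exposure year:  ", x$prevalence_year, "  cost year: ", x$cost_year, "\n")
  cat("  Monte Carlo:    ", x$mc$n_iterations, "iterations",
      if (!is.null(x$mc$seed)) paste0("(seed ", x$mc$seed, ")"), "\n\n")
  r <- x$results
  tab <- data.frame(cancer = r$cancer, sex = r$sex,
                    `PIF%` = sprintf("%.*f (%.*f-%.*f)", digits, 100 * r$pif,
                                     digits, 100 * r$pif_low, digits,
                                     100 * r$pif_high),
                    cost = round(r$cost, digits),
                    attributable = sprintf("%.*f (%.*f-%.*f)", digits,
                                           r$attributable, digits,
                                           r$attributable_low, digits,
                                           r$attributable_high),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat("\nTotals:\n")
  t <- x$totals
  print(data.frame(sex = t$sex, cost = round(t$cost, digits),
                   attributable = sprintf("%.*f (%.*f-%.*f)", digits,
                                          t$attributable, digits,
                                          t$attributable_low, digits,
                                          t$attributable_high),
                   `PIF%` = round(100 * t$pif, digits), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.ebw_attribution <- function(object, ...) {
  t <- object$totals
  structure(list(totals = t, n_cancers = length(unique(object$results$cancer)),
                 scenario = object$scenario$label,
                 n_truncated = sum(object$results$n_truncated),
                 n_iterations = object$mc$n_iterations),
            class = "summary.ebw_attribution")
}

#' @export
print.summary.ebw_attribution <- function(x, ...) {
  cat("Attribution over", x$n_cancers, "cancers, scenario:", x$scenario, "\n")
  both <- x$totals[x$totals$sex == "T", ]
  cat(sprintf("Total attributable cost: %.2f (%.2f-%.2f), overall PIF %.2f%%\n",
              both$attributable, both$attributable_low, both$attributable_high,
              100 * both$pif))
  cat(sprintf("Negative PIF draws truncated: %d of %d per-cancer draws\n",
              x$n_truncated, x$n_iterations))
  invisible(x)
}

#' @export
coef.ebw_attribution <- function(object, ...) {
  stats::setNames(object$results$pif,
                  paste(object$results$cancer, object$results$sex, sep = "/"))
}

#' Plot baseline against counterfactual BMI distribution
#'
#' Grouped bar chart of the baseline category proportions and the
#' counterfactual distribution implied by the fitted scenario, per stratum.
#'
#' @param x an `ebw_attribution` object.
#' @param stratum stratum to plot (default: first in the baseline).
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the matrix of plotted proportions.
#' @export
plot.ebw_attribution <- function(x, stratum = NULL, ...) {
  base <- x$baseline
  if (is.null(stratum)) stratum <- base$stratum[1]
  app <- suppressWarnings(apply_scenario(base, x$scenario, x$schema))
  p0 <- stratum_proportions(base, stratum, x$schema)
  p1 <- stratum_proportions(app$prevalence, stratum, x$schema)
  m <- rbind(baseline = p0, counterfactual = p1)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    xlab = "BMI category (kg/m^2)", ylab = "proportion",
                    main = paste0(stratum, ": ", x$scenario$label), ...)
  invisible(m)
}

#' @export
print.ebw_savings <- function(x, digits = 2, ...) {
  cat("Potential savings in cancer costs under counterfactual BMI scenarios\n")
  cat("  exposure year:", x$prevalence_year, "  cost year:", x$cost_year, "\n\n")
  t <- x$totals[x$totals$sex == "T", ]
  print(data.frame(scenario = t$scenario, cost = round(t$cost, digits),
                   savings = sprintf("%.*f (%.*f-%.*f)", digits, t$savings,
                                     digits, t$savings_low, digits,
                                     t$savings_high)),
        row.names = FALSE)
  invisible(x)
}
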