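#' Read tabular inputs from CSV
#'
#' Thin readers that validate on ingest. Expected columns:
#' * RR tables: `cancer, sex, increment, rr, ci_low, ci_high`
#' * prevalence tables: `stratum, category, proportion` (optionally
#'   `effective_n, year, ci_low, ci_high`)
#' * cost series: `cancer, sex, year, cost` (optionally `currency`)
#' * study lists: `study, log_rr, se` (optionally `outcome`)
#'
#' @param path CSV file path.
#' @return The validated object (`rr_table`, `prevalence_table`,
#'   `cost_series`, or a plain data frame for studies).
#' @name io
NULL

#' @rdname io
#' @export
read_rr_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cancer", "sex", "increment", "rr", "ci_low", "ci_high")
  if (!all(req %in% names(x)))
    stop("RR CSV must have columns ", paste(req, collapse = ", "), call. = FALSE)
  validate_rr_table(x[req])
}

#' @rdname io
#' @export
read_prevalence_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("stratum", "category", "proportion")
  if (!all(req %in% names(x)))
    stop("prevalence CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  for (opt in c("effective_n", "year", "ci_low", "ci_high"))
    if (!opt %in% names(x)) x[[opt]] <- NA_real_
  validate_prevalence(x[c(req, "effective_n", "year", "ci_low", "ci_high")])
}

#' @rdname io
#' @export
read_cost_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cancer", "sex", "year", "cost")
  if (!all(req %in% names(x)))
    stop("cost CSV must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (!"currency" %in% names(x)) x$currency <- "BRL"
  validate_cost_series(x[c(req, "currency")])
}

#' @rdname io
#' @export
read_studies_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study", "log_rr", "se")
  if (!all(req %in% names(x)))
    stop("study CSV must have columns ", paste(req, collapse = ", "), call. = FALSE)
  x
}

#' Read/write scenario specifications as YAML
#'
#' Serialises an `ebw_scenario` (without embedded tables; `target` and
#' `hold` scenarios reference a prevalence CSV by path).
#'
#' @param spec an `ebw_scenario`.
#' @param path YAML file path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns the `ebw_scenario`.
#' @export
write_scenario_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "ebw_scenario"))
  fields <- spec[setdiff(names(spec), c("table"))]
  if (!is.null(spec$table)) {
    csv <- sub("\\.ya?ml$", "_table.csv", path)
    utils::write.csv(spec$table, csv, row.names = FALSE)
    fields$table_csv <- basename(csv)
  }
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  table <- NULL
  if (!is.null(y$table_csv))
    table <- read_prevalence_csv(file.path(dirname(path), y$table_csv))
  switch(y$kind,
    tmrel = scenario_tmrel(),
    target = scenario_target(table),
    hold = scenario_hold(table),
    truncate = scenario_truncate(y$threshold, y$reallocate_to),
    mean_shift = scenario_mean_shift(y$shift, y$eligible_min),
    stop("unknown scenario kind in YAML: ", y$kind, call. = FALSE))
}
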