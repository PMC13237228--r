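#' @keywords internal
long_col_map <- c(country = "Country", region = "Region", period = "Year",
                  age_group = "Age Group", education = "Education",
                  value = "Value", births = "Births", exposure = "Exposure",
                  survey_year = "SurveyYear")

#' Write a long-format fertility table as CSV
#'
#' Internal snake_case columns are mapped to the published long-format
#' headers: Country, Region, Year (period label), Age Group, Education,
#' Value, and for survey tables Births, Exposure, SurveyYear.
#'
#' @param df Table with a subset of columns `country`, `region`, `period`,
#'   `age_group`, `education`, `value`, `births`, `exposure`, `survey_year`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_long_csv <- function(df, path) {
  keep <- intersect(names(long_col_map), names(df))
  out <- df[keep]
  names(out) <- unname(long_col_map[keep])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a long-format fertility table
#'
#' Parses CSVs written by [write_long_csv()], mapping the published headers
#' back to internal names and checking labels against the closed
#' vocabularies.
#'
#' @param path File path.
#' @param spec Optional [lattice_spec()]; when supplied, country and period
#'   labels are also checked against it.
#' @return Data frame with internal snake_case column names.
#' @export
read_long_csv <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  known <- names(long_col_map)[match(names(raw), unname(long_col_map))]
  if (anyNA(known)) {
    stop("unexpected column(s) in ", path, ": ",
         paste(names(raw)[is.na(known)], collapse = ", "),
         "; expected among: ", paste(long_col_map, collapse = ", "),
         call. = FALSE)
  }
  names(raw) <- known
  if ("education" %in% names(raw)) {
    vocab <- if (is.null(spec)) fert_education_levels() else
      spec$education_levels
    match_vocabulary(raw$education, vocab, "education")
  }
  if ("age_group" %in% names(raw)) {
    vocab <- if (is.null(spec)) fert_age_groups() else spec$age_groups
    match_vocabulary(raw$age_group, vocab, "age group")
  }
  if ("region" %in% names(raw)) {
    match_vocabulary(raw$region, fert_regions(), "region")
  }
  if (!is.null(spec)) {
    if ("country" %in% names(raw)) {
      match_vocabulary(raw$country, spec$countries, "country")
    }
    if ("period" %in% names(raw)) {
      match_vocabulary(raw$period, spec$periods, "period")
    }
  }
  raw
}

#' Validate a rate or weight lattice
#'
#' Checks a long-format grid against the complete lattice of a
#' [lattice_spec()]: missing cells, duplicated cells, negative values and --
#' for weight tables -- per-(country, period, age) weight sums different
#' from 1.
#'
#' @param grid Long-format table with `country`, `period`, `age_group`,
#'   `education`, `value`.
#' @param spec A [lattice_spec()].
#' @param weights Treat `grid` as a weight table and check weight sums.
#' @param tol Tolerance for weight sums (default 1e-9).
#' @return An object of class `lattice_report`: list with data frames
#'   `missing`, `duplicated`, `negative`, `weight_sum` and logical `ok`.
#' @export
validate_lattice <- function(grid, spec, weights = FALSE, tol = 1e-9) {
  full <- lattice_cells(spec)
  fk <- cell_key(full)
  gk <- cell_key(grid)
  missing <- full[!(fk %in% gk), , drop = FALSE]
  dup <- grid[duplicated(gk), c("country", "period", "age_group",
                                "education"), drop = FALSE]
  neg <- grid[!is.na(grid$value) & grid$value < 0, , drop = FALSE]
  wsum <- data.frame(country = character(), period = character(),
                     age_group = character(), sum = numeric())
  if (weights && nrow(grid)) {
    key <- cell_key(grid, c("country", "period", "age_group"))
    sums <- rowsum(grid$value, key)
    bad <- abs(sums[, 1] - 1) > tol
    if (any(bad)) {
      cells <- grid[!duplicated(key), c("country", "period", "age_group")]
      cells <- cells[match(rownames(sums), unique(key)), , drop = FALSE]
      wsum <- cells[bad, , drop = FALSE]
      wsum$sum <- sums[bad, 1]
    }
  }
  rownames(missing) <- rownames(dup) <- rownames(neg) <- rownames(wsum) <- NULL
  structure(list(missing = missing, duplicated = dup, negative = neg,
                 weight_sum = wsum,
                 ok = !(nrow(missing) || nrow(dup) || nrow(neg) ||
                          nrow(wsum))),
            class = "lattice_report")
}

#' @export
print.lattice_report <- function(x, ...) {
  if (x$ok) {
    cat("<lattice_report> OK\n")
  } else {
    cat("<lattice_report> ", nrow(x$missing), " missing, ",
        nrow(x$duplicated), " duplicated, ", nrow(x$negative),
        " negative, ", nrow(x$weight_sum), " weight-sum violations\n",
        sep = "")
  }
  invisible(x)
}

estimate_cols <- c("Country", "Age Group", "Education", "Year",
                   "Upper_CI", "Lower_CI", "Median")

#' Write posterior estimates in the published workbook schema
#'
#' Writes one row per (country, age group, education, period) with exactly
#' the columns Country, Age Group, Education, Year, Upper_CI, Lower_CI and
#' Median, in that order. The bounds are the central credible interval of the
#' summary (95\% by default upstream).
#'
#' @param summary Data frame with columns `country`, `age_group`,
#'   `education`, `period`, `median`, `lower`, `upper` (the EAFR element of
#'   [summarize_draws()]), or an object of class `posterior_summary`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_estimates <- function(summary, path) {
  if (inherits(summary, "posterior_summary")) summary <- summary$eafr
  need <- c("country", "age_group", "education", "period", "median",
            "lower", "upper")
  miss <- setdiff(need, names(summary))
  if (length(miss)) {
    stop("summary table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(summary$country, summary$age_group, summary$education,
                    summary$period, summary$upper, summary$lower,
                    summary$median, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- estimate_cols
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write estimates to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a published-schema estimates file
#'
#' @param path CSV written by [write_estimates()].
#' @return Data frame with internal columns `country`, `age_group`,
#'   `education`, `period`, `median`, `lower`, `upper`.
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(raw), estimate_cols)) {
    stop("unexpected estimates header: expected columns ",
         paste(estimate_cols, collapse = ", "), call. = FALSE)
  }
  match_vocabulary(raw$Education, fert_education_levels(), "education")
  match_vocabulary(raw$`Age Group`, fert_age_groups(), "age group")
  data.frame(country = raw$Country, age_group = raw$`Age Group`,
             education = raw$Education, period = raw$Year,
             median = raw$Median, lower = raw$Lower_CI,
             upper = raw$Upper_CI, stringsAsFactors = FALSE)
}
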