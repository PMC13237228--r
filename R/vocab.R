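#' Closed vocabularies for the fertility lattice
#'
#' The estimation lattice is a complete crossing of country, five-year period,
#' five-year age group and educational attainment. Age groups span the
#' reproductive ages 15-19 through 45-49; education uses the four attainment
#' categories of the survey programme; regions follow the seven UN regions
#' used for pooling.
#'
#' @return Character vector of labels, in canonical order.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
fert_age_groups <- function() {
  c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
}

#' @rdname vocabularies
#' @export
fert_education_levels <- function() {
  c("No Education", "Primary Education", "Secondary Education",
    "Higher Education")
}

#' @rdname vocabularies
#' @export
fert_regions <- function() {
  c("sub-Saharan Africa", "North Africa", "West Asia", "Europe",
    "Central Asia", "South & Southeast Asia", "Latin America")
}

#' Five-year period labels
#'
#' @param from,to First calendar years of the first and last period.
#' @return Labels of the form `"YYYY-YYYY"`, left-closed on calendar years.
#' @examples
#' fert_periods(1970, 2015)
#' @export
fert_periods <- function(from = 1970, to = 2015) {
  starts <- seq(from, to, by = 5)
  paste0(starts, "-", starts + 5)
}

#' @keywords internal
period_start <- function(period) {
  as.integer(sub("-.*$", "", period))
}

#' @keywords internal
period_mid <- function(period) {
  period_start(period) + 2.5
}

#' Age-group midpoints in years
#' @keywords internal
age_mid <- function(age_group) {
  lo <- as.integer(sub("-.*$", "", age_group))
  lo + 2.5
}

check_period_labels <- function(periods) {
  ok <- grepl("^[0-9]{4}-[0-9]{4}$", periods)
  if (!all(ok)) {
    stop("invalid period label(s): ", paste(periods[!ok], collapse = ", "),
         " (expected \"YYYY-YYYY\")", call. = FALSE)
  }
  span <- as.integer(sub("^.*-", "", periods)) - period_start(periods)
  if (any(span != 5L)) {
    stop("period label(s) not spanning 5 years: ",
         paste(periods[span != 5L], collapse = ", "), call. = FALSE)
  }
  invisible(periods)
}

label_synonyms <- c("tertiary" = "Higher Education",
                    "higher" = "Higher Education",
                    "university" = "Higher Education",
                    "secondary" = "Secondary Education",
                    "primary" = "Primary Education",
                    "none" = "No Education",
                    "no school" = "No Education")

match_vocabulary <- function(x, vocab, what) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad)) {
    hints <- vapply(bad, function(b) {
      syn <- unname(label_synonyms[tolower(b)])
      if (!is.na(syn) && syn %in% vocab) return(syn)
      d <- utils::adist(tolower(b), tolower(vocab), partial = TRUE)
      vocab[which.min(d)]
    }, character(1))
    stop("unknown ", what, " label(s): ",
         paste0("\"", bad, "\" (did you mean \"", hints, "\"?)",
                collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Lattice specification
#'
#' Describes the complete country x period x age x education crossing on
#' which rates are defined, together with the region of each country.
#'
#' @param countries Character vector of country names.
#' @param periods Five-year period labels (see [fert_periods()]).
#' @param age_groups Age-group labels; default the seven reproductive groups.
#' @param education_levels Education labels; default the four survey
#'   attainment categories.
#' @param region_assignment Named character vector mapping each country to one
#'   of the seven regions in [fert_regions()].
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(countries, periods,
                         age_groups = fert_age_groups(),
                         education_levels = fert_education_levels(),
                         region_assignment) {
  stopifnot(is.character(countries), length(countries) >= 1,
            !anyDuplicated(countries))
  check_period_labels(periods)
  if (is.null(names(region_assignment)) ||
      !setequal(names(region_assignment), countries)) {
    stop("region_assignment must be named by every country", call. = FALSE)
  }
  match_vocabulary(unname(region_assignment), fert_regions(), "region")
  structure(
    list(countries = countries, periods = periods, age_groups = age_groups,
         education_levels = education_levels,
         region_assignment = region_assignment[countries]),
    class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat("<lattice_spec> ", length(x$countries), " countries x ",
      length(x$periods), " periods x ", length(x$age_groups), " ages x ",
      length(x$education_levels), " educations (",
      length(x$countries) * length(x$periods) * length(x$age_groups) *
        length(x$education_levels), " cells)\n", sep = "")
  invisible(x)
}

#' Complete cell lattice as a long data frame
#'
#' @param spec A [lattice_spec()].
#' @param by_age Include the age dimension (default `TRUE`).
#' @param by_education Include the education dimension (default `TRUE`).
#' @return Data frame with columns `country`, `period` and, as requested,
#'   `age_group` and `education`, in canonical cell order (education varying
#'   fastest, then age, period, country).
#' @export
lattice_cells <- function(spec, by_age = TRUE, by_education = TRUE) {
  dims <- list()
  if (by_education) dims$education <- spec$education_levels
  if (by_age) dims$age_group <- spec$age_groups
  dims$period <- spec$periods
  dims$country <- spec$countries
  g <- expand.grid(dims, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g[, rev(names(dims)), drop = FALSE]
}

cell_key <- function(df, cols = c("country", "period", "age_group",
                                  "education")) {
  cols <- intersect(cols, names(df))
  do.call(paste, c(unname(df[cols]), sep = "\r"))
}
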