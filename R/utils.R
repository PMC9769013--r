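`%||%` <- function(a, b) if (is.null(a)) b else a

#' Labels for a set of abridged age groups
#'
#' @param age_breaks Integer vector of lower bounds of the age groups; the
#'   last entry opens the final, unbounded interval.
#' @return Character vector of labels, e.g. `"0-4"`, ..., `"95+"`.
#' @export
#' @examples
#' age_group_labels(seq(0, 95, by = 5))
age_group_labels <- function(age_breaks) {
  n <- length(age_breaks)
  c(paste0(age_breaks[-n], "-", age_breaks[-1] - 1L), paste0(age_breaks[n], "+"))
}

#' Assign single-year ages to abridged age groups
#'
#' Ages beyond the start of the open-ended interval are folded into it.
#'
#' @param age Numeric vector of ages in completed years.
#' @inheritParams age_group_labels
#' @return Ordered factor of age-group labels.
#' @export
cut_age_group <- function(age, age_breaks = seq(0, 95, by = 5)) {
  if (any(age < age_breaks[1], na.rm = TRUE)) {
    stop("ages below the first age-group boundary (", age_breaks[1], ") found")
  }
  labs <- age_group_labels(age_breaks)
  idx <- findInterval(age, age_breaks)
  factor(labs[pmin(idx, length(labs))], levels = labs, ordered = TRUE)
}

# lower bounds back from labels such as "0-4", "95+"
age_breaks_from_labels <- function(labels) {
  as.integer(sub("[-+].*$", "", as.character(labels)))
}

indicator_columns <- function(records) {
  cols <- grep("^indicator_", names(records), value = TRUE)
  if (!length(cols)) stop("no indicator columns (prefix 'indicator_') found")
  cols
}

# modal observed value of a binary deprivation indicator; ties resolved
# toward "deprived" (1), conservative for a deprivation index
modal_deprived <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  n1 <- sum(x == 1L)
  if (n1 >= length(x) - n1) 1L else 0L
}

# per-sector inhabitant totals from a population table; when a year column
# is present a single (census-like) year is used
sector_population_totals <- function(population, year = NULL) {
  P <- as.data.table(population)
  if ("year" %in% names(P)) {
    yr <- year %||% min(P$year)
    P <- P[P$year == yr]
  }
  P[, .(population = sum(count)), by = sector_id]
}
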