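#' Percent change between two period values
#'
#' `100 * (last - first) / first`, vectorized; undefined (with a warning)
#' where the baseline is zero. Rounding to presentation precision is left
#' to the caller.
#'
#' @param first,last Values in the first and last period.
#' @return Percent change.
#' @export
#' @examples
#' round(change_pct(1649, 1243), 2)
change_pct <- function(first, last) {
  out <- 100 * (last - first) / first
  zero <- !is.na(first) & first == 0
  if (any(zero)) {
    warning("percent change undefined where the baseline is zero")
    out[zero] <- NA_real_
  }
  out
}

#' Most-vs-least deprived gap with the metric's conventional orientation
#'
#' Mortality-type metrics (rates, attributable fractions, PYLL) report
#' `most - least`; life expectancy reports `least - most`, so an adverse
#' gradient is positive either way.
#'
#' @param most,least Values for the most and least deprived decile.
#' @param metric One of `"rate"`, `"paf"`, `"pyll"`, `"e0"`.
#' @return The oriented gap.
#' @export
extreme_gap <- function(most, least, metric = c("rate", "paf", "pyll", "e0")) {
  metric <- match.arg(metric)
  if (metric == "e0") least - most else most - least
}

#' Trend table for an inequality metric across periods
#'
#' Assembles the most deprived, least deprived and difference rows of a
#' metric across periods, with the change between the first and last
#' period: absolute change in years for life expectancy, percent change
#' otherwise. Values are carried at full precision; `digits` (2 for
#' rates/e0, 1 for PAF/PYLL) is attached for presentation rounding.
#'
#' @param values Data frame with columns `extreme` (`"most"`/`"least"`),
#'   `period`, `value`, plus optional grouping keys (e.g. `sex`).
#' @param metric One of `"rate"`, `"e0"`, `"paf"`, `"pyll"`.
#' @param period_first,period_last Period labels compared by the change
#'   column.
#' @return Data frame, one row per group and series (`most`, `least`,
#'   `difference`), one column per period, plus `change`.
#' @export
trend_table <- function(values, metric = c("rate", "e0", "paf", "pyll"),
                        period_first, period_last) {
  metric <- match.arg(metric)
  v <- as.data.table(values)
  keys <- setdiff(names(v), c("extreme", "period", "value"))
  periods <- unique(v$period)
  if (!all(c(period_first, period_last) %in% periods)) {
    stop("both comparison periods must be present")
  }
  gap <- v[, .(extreme = "difference",
               value = extreme_gap(value[extreme == "most"],
                                   value[extreme == "least"], metric)),
           by = c(keys, "period")]
  allv <- rbind(v[, c(keys, "extreme", "period", "value"), with = FALSE], gap)
  f <- stats::as.formula(paste(
    paste(c(keys, "extreme"), collapse = " + "), "~ period"))
  wide <- dcast(allv, f, value.var = "value")
  wide[, change := if (metric == "e0") {
    get(period_last) - get(period_first)
  } else {
    change_pct(get(period_first), get(period_last))
  }]
  wide[, extreme := factor(extreme, levels = c("most", "least", "difference"))]
  setorderv(wide, c(keys, "extreme"))
  wide[, extreme := as.character(extreme)]
  out <- setDF(wide)
  attr(out, "metric") <- metric
  attr(out, "digits") <- if (metric %in% c("rate", "e0")) 2L else 1L
  attr(out, "change") <- if (metric == "e0") "absolute (years)" else "percent"
  out
}
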