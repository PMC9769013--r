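#' Stratify deaths and person-years by age group, sex, decile and period
#'
#' Deaths are counted into the stratum of their age group (ages beyond the
#' open interval's start are folded into it), sex, the deprivation decile of
#' their sector, and the period containing their year. Person-years are the
#' sum of annual mid-year population counts over the period's years. The
#' complete cross-product of strata is emitted, with zero deaths where none
#' occurred. Deaths in excluded (unassigned) sectors or outside the periods
#' are dropped with a logged count.
#'
#' @param deaths Death records with `sector_id`, `sex`, `age_at_death` (or
#'   `age`) and `year`.
#' @param population Mid-year population counts: `sector_id`, `sex`, `age`,
#'   `year`, `count`.
#' @param assignment Decile assignment (see [assign_deciles()]).
#' @param periods Named list of integer year vectors.
#' @param age_breaks Lower bounds of the analysis age groups; the last
#'   opens the final interval (default 0-4, ..., 95+).
#' @return Data frame with one row per `(age_group, sex, decile, period)`:
#'   `deaths`, `person_years`. Dropped-death counts are attached as the
#'   `"dropped"` attribute.
#' @export
stratify <- function(deaths, population, assignment, periods,
                     age_breaks = seq(0, 95, by = 5)) {
  if (!is.list(periods) || is.null(names(periods))) {
    stop("`periods` must be a named list of year vectors")
  }
  asn <- assignment[!is.na(assignment$decile), , drop = FALSE]
  labs <- age_group_labels(age_breaks)
  yrs <- unlist(periods, use.names = FALSE)
  per_of_year <- rep(names(periods), lengths(periods))

  D <- as.data.table(deaths)
  agecol <- if ("age_at_death" %in% names(D)) "age_at_death" else "age"
  D[, decile := asn$decile[match(sector_id, asn$sector_id)]]
  n_excl <- sum(is.na(D$decile))
  if (n_excl) {
    message("dropped ", n_excl, " death(s) in excluded or unknown sectors")
  }
  D <- D[!is.na(decile)]
  D[, period := per_of_year[match(year, yrs)]]
  n_out <- sum(is.na(D$period))
  if (n_out) message("dropped ", n_out, " death(s) outside the analysis periods")
  D <- D[!is.na(period)]
  D[, age_group := cut_age_group(get(agecol), age_breaks)]
  dsum <- D[, .(deaths = .N), by = .(age_group, sex, decile, period)]

  P <- as.data.table(population)
  P[, decile := asn$decile[match(sector_id, asn$sector_id)]]
  P <- P[!is.na(decile)]
  P[, period := per_of_year[match(year, yrs)]]
  P <- P[!is.na(period)]
  P[, age_group := cut_age_group(age, age_breaks)]
  py <- P[, .(person_years = as.double(sum(count))),
          by = .(age_group, sex, decile, period)]

  grid <- CJ(
    age_group = factor(labs, levels = labs, ordered = TRUE),
    sex = sort(unique(P$sex)),
    decile = sort(unique(asn$decile)),
    period = names(periods)
  )
  out <- merge(grid, dsum, by = c("age_group", "sex", "decile", "period"),
               all.x = TRUE)
  out <- merge(out, py, by = c("age_group", "sex", "decile", "period"),
               all.x = TRUE)
  out[is.na(deaths), deaths := 0L]
  out[is.na(person_years), person_years := 0]
  if (any(out$person_years == 0)) {
    message("note: ", sum(out$person_years == 0),
            " strata have zero person-years; ",
            "rate-based operations on them will fail")
  }
  setorder(out, period, sex, decile, age_group)
  setDF(out)
  attr(out, "dropped") <- c(excluded_sector = n_excl, outside_period = n_out)
  out
}

#' Standard population weights from a population table
#'
#' Derives the (age group x sex) weight structure of a reference population
#' (e.g. the national population of a recent year), normalized to sum to 1.
#'
#' @inheritParams stratify
#' @param year Reference year; default the latest year present.
#' @return Data frame with `age_group`, `sex`, `weight`.
#' @export
standard_population <- function(population, year = NULL,
                                age_breaks = seq(0, 95, by = 5)) {
  P <- as.data.table(population)
  if ("year" %in% names(P)) {
    yr <- year %||% max(P$year)
    P <- P[P$year == yr]
  }
  P[, age_group := cut_age_group(age, age_breaks)]
  w <- P[, .(count = sum(count)), by = .(age_group, sex)]
  grid <- CJ(age_group = factor(age_group_labels(age_breaks),
                                levels = age_group_labels(age_breaks),
                                ordered = TRUE),
             sex = sort(unique(P$sex)))
  w <- merge(grid, w, by = c("age_group", "sex"), all.x = TRUE)
  w[is.na(count), count := 0]
  w[, weight := count / sum(count)]
  setDF(w[, .(age_group, sex, weight)])
}

#' Directly age- and sex-standardized mortality rates
#'
#' Computes `per x sum(w_a * D_a / PY_a)` over the standardization cells of
#' each output group, with the Poisson variance `per^2 * sum(w_a^2 * D_a /
#' PY_a^2)` and a normal-approximation confidence interval truncated at 0.
#' Weights are renormalized within each output group, so sex-specific rates
#' use within-sex weights and pooled rates use the joint age x sex weights;
#' the rate is invariant to rescaling all weights by a constant.
#'
#' @param strata Stratum table from [stratify()].
#' @param standard Standard population (see [standard_population()]).
#' @param per Scale of the reported rate (default per 100,000 person-years).
#' @param by Grouping columns of the output, a subset of
#'   `c("decile", "sex", "period")`.
#' @param conf_level Confidence level for the interval.
#' @return Data frame with the group keys, `rate`, `ci_low`, `ci_high`.
#' @export
direct_standardize <- function(strata, standard, per = 1e5,
                               by = c("decile", "sex", "period"),
                               conf_level = 0.95) {
  by <- intersect(by, names(strata))
  dt <- as.data.table(strata)
  std <- as.data.table(standard)
  dt <- merge(dt, std[, .(age_group, sex, weight)],
              by = c("age_group", "sex"), all.x = TRUE)
  if (anyNA(dt$weight)) {
    bad <- dt[is.na(weight)][1]
    stop("standard population has no weight for cell age ", bad$age_group,
         ", sex ", bad$sex)
  }
  cell_by <- unique(c(by, "age_group", "sex"))
  agg <- dt[, .(deaths = sum(deaths), person_years = sum(person_years),
                weight = weight[1]), by = cell_by]
  bad <- agg[person_years <= 0 & weight > 0]
  if (nrow(bad)) {
    stop("zero person-years with positive standard weight in cell age ",
         bad$age_group[1], ", sex ", bad$sex[1],
         if ("decile" %in% names(bad)) paste0(", decile ", bad$decile[1]) else "",
         if ("period" %in% names(bad)) paste0(", period ", bad$period[1]) else "")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  grp <- if (length(by)) by else NULL
  est <- agg[, {
    wn <- weight / sum(weight)
    r <- per * sum(ifelse(wn > 0, wn * deaths / person_years, 0))
    v <- per^2 * sum(ifelse(wn > 0, wn^2 * deaths / person_years^2, 0))
    se <- sqrt(v)
    .(rate = r, ci_low = max(0, r - z * se), ci_high = r + z * se)
  }, by = grp]
  if (length(by)) setorderv(est, by)
  setDF(est)
  attr(est, "per") <- per
  est
}

#' Change in standardized rates between two periods
#'
#' Per group, the absolute change `last - first` and the percent change
#' `100 * (last - first) / first`; when a `decile` column is present, the
#' most-vs-least deprived "difference" series (most minus least, per
#' period) and its change across the two periods are also returned.
#'
#' @param estimates Output of [direct_standardize()] with a `period` column.
#' @param period_first,period_last Period labels to compare.
#' @return List with `change` (per group), and, when deciles are present,
#'   `gap` (per period) and `gap_change`.
#' @export
asmr_change <- function(estimates, period_first, period_last) {
  est <- as.data.table(estimates)
  if (!all(c(period_first, period_last) %in% est$period)) {
    stop("both periods must be present in `estimates`")
  }
  keys <- setdiff(names(est), c("period", "rate", "ci_low", "ci_high"))
  f <- est[period == period_first, c(keys, "rate"), with = FALSE]
  setnames(f, "rate", "rate_first")
  l <- est[period == period_last, c(keys, "rate"), with = FALSE]
  setnames(l, "rate", "rate_last")
  ch <- if (length(keys)) merge(f, l, by = keys) else cbind(f, l)
  ch[, change_abs := rate_last - rate_first]
  ch[, change_pct := change_pct(rate_first, rate_last)]

  gap <- NULL
  gap_change <- NULL
  if ("decile" %in% names(est)) {
    gkeys <- setdiff(keys, "decile")
    gsel <- c(gkeys, "period")
    gap <- est[decile %in% range(decile), {
      .(most = rate[decile == min(est$decile)],
        least = rate[decile == max(est$decile)])
    }, by = gsel]
    gap[, difference := most - least]
    gf <- gap[period == period_first]
    gl <- gap[period == period_last]
    gap_change <- if (length(gkeys)) {
      merge(gf[, c(gkeys, "difference"), with = FALSE],
            gl[, c(gkeys, "difference"), with = FALSE],
            by = gkeys, suffixes = c("_first", "_last"))
    } else {
      data.table(difference_first = gf$difference,
                 difference_last = gl$difference)
    }
    gap_change[, change_abs := difference_last - difference_first]
    gap_change[, change_pct := change_pct(difference_first, difference_last)]
    gap <- setDF(gap)
    gap_change <- setDF(gap_change)
  }
  list(change = setDF(ch), gap = gap, gap_change = gap_change)
}
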