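#' Adjusted Lorenz curve across deprivation deciles
#'
#' Per decile, standardized deaths are the decile's age/sex-standardized
#' rate times its person-years; the curve accumulates population share and
#' standardized-death share over deciles ordered from most to least
#' deprived, prepending the point (0, 0). With `standardized = FALSE` crude
#' death counts are accumulated instead.
#'
#' @inheritParams direct_standardize
#' @param by Grouping columns (curves are computed per group).
#' @param standardized Use standardized (default) or crude deaths.
#' @return Data frame with the group keys, `decile` (0 for the origin),
#'   `cum_pop_share`, `cum_death_share`.
#' @export
lorenz_points <- function(strata, standard, by = c("sex", "period"),
                          per = 1e5, standardized = TRUE) {
  by <- intersect(by, names(strata))
  dd <- as.data.table(strata)[, .(
    person_years = sum(person_years),
    crude_deaths = sum(deaths)
  ), by = c(by, "decile")]
  if (standardized) {
    est <- as.data.table(direct_standardize(strata, standard, per = per,
                                            by = c(by, "decile")))
    dd <- merge(dd, est[, c(by, "decile", "rate"), with = FALSE],
                by = c(by, "decile"))
    dd[, std_deaths := rate / per * person_years]
  } else {
    dd[, std_deaths := as.double(crude_deaths)]
  }
  setorderv(dd, c(by, "decile")) # decile 1 = most deprived accumulates first
  grp <- if (length(by)) by else NULL
  curve <- dd[, {
    if (sum(std_deaths) <= 0) {
      stop("zero total deaths in a Lorenz group; curve undefined")
    }
    .(decile = c(0L, decile),
      cum_pop_share = c(0, cumsum(person_years) / sum(person_years)),
      cum_death_share = c(0, cumsum(std_deaths) / sum(std_deaths)))
  }, by = grp]
  setDF(curve)
  curve
}

#' Gini coefficient of a Lorenz curve
#'
#' Trapezoid estimator on the 11-point decile curve:
#' `G = |1 - sum_k (x_k - x_{k-1}) (y_k + y_{k-1})|`.
#'
#' @param curve Output of [lorenz_points()].
#' @return Data frame with the group keys and `gini`.
#' @export
gini <- function(curve) {
  dt <- as.data.table(curve)
  keys <- setdiff(names(dt), c("decile", "cum_pop_share", "cum_death_share"))
  grp <- if (length(keys)) keys else NULL
  out <- dt[, {
    x <- cum_pop_share
    y <- cum_death_share
    if (is.unsorted(x) || is.unsorted(y) ||
        min(x, y) < -1e-12 || abs(x[1]) > 1e-12 || abs(y[1]) > 1e-12 ||
        abs(x[.N] - 1) > 1e-9 || abs(y[.N] - 1) > 1e-9) {
      stop("Lorenz points are not an ordered cumulative curve from (0,0) to (1,1)")
    }
    .(gini = abs(1 - sum(diff(x) * (y[-1] + y[-.N]))))
  }, by = grp]
  setDF(out)
  out
}

#' Counterfactual expected deaths under the least deprived decile's rates
#'
#' Applies the reference decile's age/sex/period-specific death rates to
#' every decile's person-years. For the reference decile itself this
#' reproduces the observed deaths exactly, so its excess is zero.
#'
#' @inheritParams direct_standardize
#' @param reference_decile Reference decile; defaults to the largest decile
#'   number (the least deprived under the 1 = most deprived convention).
#' @return `strata` with an `expected` column appended.
#' @export
expected_deaths <- function(strata, reference_decile = NULL) {
  st <- as.data.table(strata)
  ref <- reference_decile %||% max(st$decile)
  key <- paste(st$age_group, st$sex, st$period, sep = "|")
  refrows <- which(st$decile == ref)
  if (!length(refrows)) stop("reference decile ", ref, " absent from strata")
  ridx <- refrows[match(key, key[refrows])]
  if (anyNA(ridx)) {
    miss <- which(is.na(ridx))[1]
    stop("reference decile has no row for cell age ", st$age_group[miss],
         ", sex ", st$sex[miss], ", period ", st$period[miss])
  }
  refpy <- st$person_years[ridx]
  if (any(refpy <= 0)) {
    b <- which(refpy <= 0)[1]
    stop("reference decile has zero person-years in cell age ",
         st$age_group[b], ", sex ", st$sex[b], ", period ", st$period[b])
  }
  st[, expected := deaths[ridx] / refpy * person_years]
  out <- setDF(st)
  attr(out, "reference_decile") <- ref
  out
}

#' Population attributable fraction and excess deaths
#'
#' Aggregates observed and expected deaths over the requested grouping and
#' reports `excess = observed - expected` and `paf = excess / observed`.
#'
#' @param strata Stratum table carrying an `expected` column (see
#'   [expected_deaths()]).
#' @param by Grouping columns (use `c("sex", "period", "decile")` for
#'   decile-level results, `character(0)` for the overall total).
#' @return Data frame with group keys, `observed`, `expected`, `excess`,
#'   `paf`.
#' @export
paf_and_excess <- function(strata, by = c("sex", "period")) {
  if (!"expected" %in% names(strata)) {
    stop("`strata` must carry an `expected` column; run expected_deaths() first")
  }
  st <- as.data.table(strata)
  by <- intersect(by, names(st))
  grp <- if (length(by)) by else NULL
  out <- st[, .(observed = sum(deaths), expected = sum(expected)),
            by = grp]
  out[, excess := observed - expected]
  out[, paf := ifelse(observed > 0, excess / observed, NA_real_)]
  if (anyNA(out$paf)) {
    warning("groups with zero observed deaths: attributable fraction undefined")
  }
  if (length(by)) setorderv(out, by)
  setDF(out)
}

#' Monte Carlo confidence intervals for the attributable fraction
#'
#' In each replicate every stratum's death count is resampled from a
#' Poisson distribution with mean equal to its observed count — including
#' the reference decile, whose resampled rates define the replicate's
#' counterfactual — and the attributable fraction and excess deaths are
#' recomputed. The interval is the 2.5th/97.5th percentile over replicates
#' (at the default confidence level).
#'
#' @inheritParams expected_deaths
#' @param n_reps Number of Monte Carlo replicates (at least 100).
#' @param seed Optional seed for reproducibility.
#' @param by Grouping columns of the reported results.
#' @param conf_level Confidence level.
#' @return Data frame with group keys, point estimates (`observed`,
#'   `expected`, `excess`, `paf`) and percentile bounds `paf_ci_low`,
#'   `paf_ci_high`, `excess_ci_low`, `excess_ci_high`; the replicate
#'   standard error of the attributable fraction is in `paf_se`.
#' @export
monte_carlo_ci <- function(strata, n_reps = 10000, seed = NULL,
                           by = c("sex", "period"), reference_decile = NULL,
                           conf_level = 0.95) {
  if (n_reps < 100) stop("`n_reps` must be at least 100 for stable percentiles")
  if (!is.null(seed)) set.seed(seed)
  st <- as.data.table(strata)
  ref <- reference_decile %||% max(st$decile)
  key <- paste(st$age_group, st$sex, st$period, sep = "|")
  refrows <- which(st$decile == ref)
  ridx <- refrows[match(key, key[refrows])]
  if (anyNA(ridx)) stop("reference decile missing strata cells")
  refpy <- st$person_years[ridx]
  if (any(refpy <= 0)) stop("reference decile has zero person-years in a cell")

  nS <- nrow(st)
  D <- st$deaths
  PY <- st$person_years
  Dm <- matrix(rpois(nS * n_reps, rep(D, n_reps)), nrow = nS)
  Em <- Dm[ridx, , drop = FALSE] / refpy * PY

  by <- intersect(by, names(st))
  g <- if (length(by)) {
    do.call(paste, c(st[, by, with = FALSE], sep = "|"))
  } else {
    rep("ALL", nS)
  }
  og <- rowsum(Dm, g)
  eg <- rowsum(Em, g)
  xg <- og - eg
  pafm <- xg / og
  a <- (1 - conf_level) / 2
  paf_ci <- t(apply(pafm, 1, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  x_ci <- t(apply(xg, 1, quantile, probs = c(a, 1 - a)))
  paf_se <- apply(pafm, 1, stats::sd, na.rm = TRUE)

  # point estimates from the observed counts
  e0 <- D[ridx] / refpy * PY
  obs_g <- rowsum(D, g)[, 1]
  exp_g <- rowsum(e0, g)[, 1]
  ord <- rownames(og)
  first <- !duplicated(g)
  keydf <- if (length(by)) {
    kd <- st[first, by, with = FALSE]
    kd[match(ord, g[first])]
  } else {
    NULL
  }
  out <- data.table(
    observed = obs_g[ord],
    expected = exp_g[ord],
    excess = obs_g[ord] - exp_g[ord],
    paf = (obs_g[ord] - exp_g[ord]) / obs_g[ord],
    paf_ci_low = paf_ci[, 1],
    paf_ci_high = paf_ci[, 2],
    paf_se = paf_se,
    excess_ci_low = x_ci[, 1],
    excess_ci_high = x_ci[, 2]
  )
  if (!is.null(keydf)) out <- cbind(keydf, out)
  if (length(by)) setorderv(out, by)
  setDF(out)
  attr(out, "n_reps") <- n_reps
  attr(out, "reference_decile") <- ref
  out
}
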