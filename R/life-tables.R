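default_ax <- function(age_breaks) {
  n_w <- diff(age_breaks)
  a <- c(n_w / 2, NA_real_) # open interval filled from 1/m
  if (age_breaks[1] == 0) {
    if (length(n_w) && n_w[1] == 5) a[1] <- 2.0 # early-childhood concentration
    if (length(n_w) && n_w[1] == 1) {
      a[1] <- 0.1
      if (length(n_w) > 1 && age_breaks[2] == 1 && n_w[2] == 4) a[2] <- 1.4
    }
  }
  a
}

#' Abridged period life table
#'
#' Standard abridged life-table recursion from age-group death rates
#' `m_x = D_x / PY_x`: death probabilities
#' `q_x = n m_x / (1 + (n - a_x) m_x)` (1 in the open interval), survivors
#' `l_x` from a radix of 100,000, deaths `d_x`, person-years lived
#' `L_x = n l_{x+n} + a_x d_x` (`l_x / m_x` in the open interval),
#' `T_x` and remaining life expectancy `e_x = T_x / l_x`.
#'
#' The default `a_x` convention is `n/2` for closed intervals except the
#' first (2.0 for a 0-4 group, reflecting the concentration of deaths in
#' infancy; 0.1 for a `<1` group, then 1.4 for 1-4), and `1/m` in the open
#' interval.
#'
#' @param deaths Death counts per age group.
#' @param person_years Person-years of exposure per age group (all > 0).
#' @param age_breaks Lower bounds of the age groups.
#' @param ax Optional mean years lived in the interval by those dying; the
#'   open-interval entry may be `NA` (filled with `1/m`).
#' @param radix Life-table radix (default 100,000).
#' @return Data frame of class `"life_table"` with columns `age`,
#'   `age_group`, `n`, `mx`, `ax`, `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex`.
#' @export
#' @examples
#' lt <- life_table(deaths = rep(200, 20), person_years = rep(1e4, 20))
#' lt$ex[1] # life expectancy at birth under a flat hazard of 0.02
life_table <- function(deaths, person_years, age_breaks = seq(0, 95, by = 5),
                       ax = NULL, radix = 1e5) {
  k <- length(age_breaks)
  if (length(deaths) != k || length(person_years) != k) {
    stop("`deaths` and `person_years` must have one value per age group")
  }
  if (any(deaths < 0) || any(person_years <= 0)) {
    stop("negative deaths or non-positive person-years")
  }
  m <- deaths / person_years
  if (m[k] <= 0) {
    stop("death rate in the open age interval is zero; life table cannot close")
  }
  n_w <- c(diff(age_breaks), Inf)
  a <- ax %||% default_ax(age_breaks)
  if (length(a) != k) stop("`ax` must have one value per age group")
  a[k] <- 1 / m[k]

  q <- n_w[-k] * m[-k] / (1 + (n_w[-k] - a[-k]) * m[-k])
  q <- pmin(q, 1)
  q <- c(q, 1)
  l <- radix * cumprod(c(1, 1 - q[-k]))
  d <- l * q
  L <- c(n_w[-k] * l[-1] + a[-k] * d[-k], 0)
  L[k] <- l[k] / m[k]
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, NA_real_)

  out <- data.frame(
    age = age_breaks,
    age_group = age_group_labels(age_breaks),
    n = n_w,
    mx = m, ax = a, qx = q, lx = l, dx = d, Lx = L, Tx = Tx, ex = e,
    stringsAsFactors = FALSE
  )
  class(out) <- c("life_table", "data.frame")
  attr(out, "radix") <- radix
  out
}

#' Life table for one sex, decile and period of a stratum table
#'
#' @inheritParams direct_standardize
#' @param sex,decile,period Keys selecting the subpopulation.
#' @param ... Passed to [life_table()].
#' @return A `"life_table"` with the keys attached as attributes.
#' @export
build_life_table <- function(strata, sex, decile, period, ...) {
  s <- strata[strata$sex == sex & strata$decile == decile &
                strata$period == period, , drop = FALSE]
  if (!nrow(s)) stop("no strata for sex ", sex, ", decile ", decile,
                     ", period ", period)
  s <- s[order(age_breaks_from_labels(s$age_group)), , drop = FALSE]
  breaks <- age_breaks_from_labels(s$age_group)
  lt <- life_table(s$deaths, s$person_years, age_breaks = breaks, ...)
  attr(lt, "sex") <- sex
  attr(lt, "decile") <- decile
  attr(lt, "period") <- period
  lt
}

#' Life expectancy at birth for every sex, decile and period
#'
#' @inheritParams direct_standardize
#' @param ... Passed to [life_table()].
#' @return Data frame with `sex`, `decile`, `period`, `e0`.
#' @export
life_expectancy_table <- function(strata, ...) {
  combos <- unique(strata[, c("sex", "decile", "period")])
  combos$e0 <- vapply(seq_len(nrow(combos)), function(i) {
    lt <- build_life_table(strata, combos$sex[i], combos$decile[i],
                           combos$period[i], ...)
    lt$ex[1]
  }, numeric(1))
  combos[order(combos$period, combos$sex, combos$decile), , drop = FALSE]
}

#' Arriaga decomposition of a life-expectancy gap by age
#'
#' Decomposes `e0(least deprived) - e0(most deprived)` into additive
#' age-group contributions. For closed intervals the direct effect is
#' `(l1_x / l0) (L2_x / l2_x - L1_x / l1_x)` and the indirect-plus-
#' interaction effect `(T2_{x+n} / l0) (l1_x / l2_x - l1_{x+n} / l2_{x+n})`;
#' the open interval contributes `(l1_x / l0) (T2_x / l2_x - T1_x / l1_x)`.
#' Table 1 is the most deprived, table 2 the least deprived, and `l0` the
#' common radix. Contributions sum exactly to the gap.
#'
#' @param lt_most,lt_least Life tables (see [build_life_table()]) on the
#'   same age grid and radix.
#' @return Data frame with `age_group`, `direct`, `indirect`, `total`;
#'   the gap `e0(least) - e0(most)` is the `"delta_e0"` attribute.
#' @export
arriaga_decompose <- function(lt_most, lt_least) {
  if (!identical(as.character(lt_most$age_group),
                 as.character(lt_least$age_group))) {
    stop("life tables are on different age grids")
  }
  if (!isTRUE(all.equal(lt_most$lx[1], lt_least$lx[1]))) {
    stop("life tables have different radices")
  }
  l0 <- lt_most$lx[1]
  k <- nrow(lt_most)
  l1 <- lt_most$lx;  L1 <- lt_most$Lx;  T1 <- lt_most$Tx
  l2 <- lt_least$lx; L2 <- lt_least$Lx; T2 <- lt_least$Tx

  direct <- numeric(k)
  indirect <- numeric(k)
  cl <- seq_len(k - 1)
  direct[cl] <- (l1[cl] / l0) * (L2[cl] / l2[cl] - L1[cl] / l1[cl])
  indirect[cl] <- (T2[cl + 1] / l0) * (l1[cl] / l2[cl] - l1[cl + 1] / l2[cl + 1])
  direct[k] <- (l1[k] / l0) * (T2[k] / l2[k] - T1[k] / l1[k])

  out <- data.frame(
    age_group = lt_most$age_group,
    direct = direct,
    indirect = indirect,
    total = direct + indirect,
    stringsAsFactors = FALSE
  )
  attr(out, "delta_e0") <- lt_least$ex[1] - lt_most$ex[1]
  out
}

#' Potential years of life lost before a cutoff age
#'
#' Life-table-cohort PYLL per person born:
#' `sum over groups ending at or before the cutoff of
#' d_x * (cutoff - (x + a_x)) / l_0`.
#'
#' @param lt A `"life_table"`.
#' @param cutoff Cutoff age; must be an age-group boundary (default 75).
#' @return Mean PYLL per person (numeric scalar).
#' @export
pyll <- function(lt, cutoff = 75) {
  breaks <- lt$age
  if (!cutoff %in% breaks) {
    stop("`cutoff` must coincide with an age-group boundary")
  }
  sel <- which(breaks + lt$n <= cutoff)
  if (!length(sel)) return(0)
  sum(lt$dx[sel] * (cutoff - (breaks[sel] + lt$ax[sel]))) / lt$lx[1]
}

#' Mean PYLL for every sex, decile and period
#'
#' @inheritParams direct_standardize
#' @inheritParams pyll
#' @param ... Passed to [life_table()].
#' @return Data frame with `sex`, `decile`, `period`, `mean_pyll`.
#' @export
pyll_table <- function(strata, cutoff = 75, ...) {
  combos <- unique(strata[, c("sex", "decile", "period")])
  combos$mean_pyll <- vapply(seq_len(nrow(combos)), function(i) {
    lt <- build_life_table(strata, combos$sex[i], combos$decile[i],
                           combos$period[i], ...)
    pyll(lt, cutoff)
  }, numeric(1))
  combos[order(combos$period, combos$sex, combos$decile), , drop = FALSE]
}

#' PYLL attributable to deprivation inequality
#'
#' Per decile, the attributable PYLL is the decile's mean PYLL minus the
#' reference (least deprived) decile's. The summary reports the
#' population-weighted all-decile mean, the counterfactual mean (everyone
#' at the reference decile's PYLL) and the attributable share
#' `(mean - counterfactual) / mean`.
#'
#' @param pyll_by_decile Data frame from [pyll_table()] (columns `decile`,
#'   `mean_pyll`, plus any grouping keys such as `sex`, `period`).
#' @param reference_decile Defaults to the largest decile number.
#' @param weights Optional data frame with the same keys plus `weight`
#'   (e.g. person-years per decile); equal weights when omitted.
#' @return List with `by_decile` (adds `attributable_pyll`) and `summary`
#'   (per group: `mean_pyll`, `counterfactual_pyll`, `attributable_pyll`,
#'   `share_attributable`).
#' @export
pyll_inequality <- function(pyll_by_decile, reference_decile = NULL,
                            weights = NULL) {
  dt <- as.data.table(pyll_by_decile)
  ref <- reference_decile %||% max(dt$decile)
  keys <- setdiff(names(dt), c("decile", "mean_pyll"))
  if (is.null(weights)) {
    dt[, w := 1]
  } else {
    wdt <- as.data.table(weights)
    dt <- merge(dt, wdt, by = intersect(names(wdt), c(keys, "decile")))
    setnames(dt, "weight", "w")
  }
  grp <- if (length(keys)) keys else NULL
  dt[, attributable_pyll := mean_pyll - mean_pyll[decile == ref], by = grp]
  summ <- dt[, {
    mu <- sum(w * mean_pyll) / sum(w)
    cf <- mean_pyll[decile == ref]
    .(mean_pyll = mu, counterfactual_pyll = cf,
      attributable_pyll = mu - cf,
      share_attributable = (mu - cf) / mu)
  }, by = grp]
  list(
    by_decile = setDF(dt[, c(keys, "decile", "mean_pyll", "attributable_pyll"),
                         with = FALSE]),
    summary = setDF(summ)
  )
}
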