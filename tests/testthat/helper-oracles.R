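# Independent oracles and small fixtures used across the suite.
# These deliberately share no helpers with the package code paths they check.

# a plausible random mortality schedule: noisy Gompertz on 20 age groups,
# capped so q < 1 in closed intervals (survivorship reaches the open group)
random_schedule <- function() {
  a <- exp(runif(1, log(2e-5), log(2e-4)))
  b <- runif(1, 0.06, 0.10)
  m <- a * exp(b * seq(0, 95, 5)) * exp(rnorm(20, 0, 0.15))
  pmin(m, 0.35)
}

# brute-force abridged life-table recursion: plain sequential loop
oracle_e0 <- function(deaths, person_years, age_breaks = seq(0, 95, by = 5),
                      a0 = 2.0, radix = 1e5) {
  k <- length(age_breaks)
  m <- deaths / person_years
  widths <- c(diff(age_breaks), NA)
  l <- numeric(k); d <- numeric(k); L <- numeric(k)
  l[1] <- radix
  for (i in seq_len(k)) {
    if (i < k) {
      n <- widths[i]
      a <- if (i == 1 && age_breaks[1] == 0 && n == 5) a0 else n / 2
      q <- n * m[i] / (1 + (n - a) * m[i])
      if (q > 1) q <- 1
      d[i] <- l[i] * q
      L[i] <- n * (l[i] - d[i]) + a * d[i]
      l[i + 1] <- l[i] - d[i]
    } else {
      d[i] <- l[i]
      L[i] <- l[i] / m[i]
    }
  }
  T0 <- 0
  for (i in k:1) T0 <- T0 + L[i]
  T0 / radix
}

# polygon (shoelace) Gini: twice the area between the curve and the diagonal
oracle_gini_polygon <- function(x, y) {
  px <- c(x, rev(x))
  py <- c(y, rev(x)) # back along the diagonal y = x
  n <- length(px)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + px[i] * py[j] - px[j] * py[i]
  }
  abs(s)
}

# Cohen's weighted kappa (quadratic weights) on two decile assignments
weighted_kappa <- function(a, b, K = 10) {
  O <- table(factor(a, levels = 1:K), factor(b, levels = 1:K))
  n <- sum(O)
  W <- 1 - (outer(1:K, 1:K, "-") / (K - 1))^2
  E <- outer(rowSums(O), colSums(O)) / n
  1 - sum((1 - W) * O) / sum((1 - W) * E)
}

# direct standardization by an explicit loop over age/sex cells
oracle_asmr_loop <- function(strata, standard, per = 1e5) {
  tot_w <- 0
  for (r in seq_len(nrow(standard))) tot_w <- tot_w + standard$weight[r]
  acc <- 0
  for (r in seq_len(nrow(standard))) {
    sel <- strata$age_group == standard$age_group[r] &
      strata$sex == standard$sex[r]
    D <- sum(strata$deaths[sel])
    PY <- sum(strata$person_years[sel])
    w <- standard$weight[r] / tot_w
    if (w > 0) acc <- acc + w * D / PY
  }
  per * acc
}

# small stratum table with arbitrary per-decile hazards, built by hand
make_strata <- function(rates_by_decile, py = 1e5,
                        age_breaks = seq(0, 95, by = 5),
                        sexes = "male", periods = "P1",
                        age_gradient = TRUE, sample_deaths = FALSE) {
  labs <- age_group_labels(age_breaks)
  base <- if (age_gradient) 2e-4 * exp(0.08 * age_breaks) else
    rep(0.01, length(age_breaks))
  out <- expand.grid(
    age_group = factor(labs, levels = labs, ordered = TRUE),
    sex = sexes, decile = as.integer(names(rates_by_decile)),
    period = periods, stringsAsFactors = FALSE
  )
  out$person_years <- py
  lam <- py * base[match(out$age_group, labs)] *
    rates_by_decile[as.character(out$decile)]
  out$deaths <- if (sample_deaths) rpois(nrow(out), lam) else round(lam)
  out
}

# equal joint standard weights over the cells of a stratum table
flat_standard <- function(strata) {
  cells <- unique(strata[, c("age_group", "sex")])
  cells$weight <- 1 / nrow(cells)
  cells
}

tiny_config <- function(n_sectors = 60, median_sector_pop = 60, seed = 1, ...) {
  generator_config(n_sectors = n_sectors, median_sector_pop = median_sector_pop,
                   seed = seed, ...)
}

# minimal housing record table built by hand
make_records <- function(values, sector = "S1", household = NULL) {
  # values: matrix persons x indicators (1/0/NA)
  values <- as.matrix(values)
  n <- nrow(values)
  df <- data.frame(
    person_id = sprintf("P%03d", seq_len(n)),
    household_id = household %||% sprintf("H%03d", seq_len(n)),
    sector_id = rep_len(sector, n),
    sex = rep_len("female", n),
    age = rep_len(40L, n),
    stringsAsFactors = FALSE
  )
  colnames(values) <- paste0("indicator_", seq_len(ncol(values)))
  cbind(df, values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
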