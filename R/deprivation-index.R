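#' Impute missing indicators from household members
#'
#' A missing indicator value is replaced by the modal observed value of the
#' same indicator among the other members of the household (ties resolved
#' toward "deprived"). Observed values are never changed; a person whose
#' household has no observed value for the indicator passes through.
#'
#' @param records Housing record table with `household_id` and
#'   `indicator_*` columns coded 1 (deprived), 0 (not deprived) or `NA`.
#' @return `records` with household-imputable values filled in.
#' @export
impute_household <- function(records) {
  if (!"household_id" %in% names(records)) stop("`household_id` column required")
  cols <- indicator_columns(records)
  DT <- as.data.table(records)
  for (cl in cols) {
    DT[, (cl) := {
      v <- .SD[[1L]]
      if (anyNA(v) && !all(is.na(v))) {
        n1 <- sum(v == 1L, na.rm = TRUE)
        n0 <- sum(v == 0L, na.rm = TRUE)
        v[is.na(v)] <- if (n1 >= n0) 1L else 0L
      }
      v
    }, by = household_id, .SDcols = cl]
  }
  setDF(DT)
  DT
}

#' Impute missing indicators from sector-mates with a similar housing profile
#'
#' For a person with a missing indicator, candidate donors are the persons
#' in the same statistical sector who observed that indicator and whose
#' observed indicators agree with the recipient's on at least
#' `share_threshold` of the indicators observed by both. The missing value
#' takes the donors' modal value (ties toward "deprived"); it stays missing
#' when no donor qualifies or the recipient has no observed indicator at
#' all. Donor values are the pre-imputation observations, so the result does
#' not depend on processing order.
#'
#' @inheritParams impute_household
#' @param share_threshold Minimum agreement share in `(0, 1]`; default 0.75.
#' @return `records` with profile-imputable values filled in.
#' @export
impute_profile <- function(records, share_threshold = 0.75) {
  if (share_threshold <= 0 || share_threshold > 1) {
    stop("`share_threshold` must be in (0, 1]")
  }
  if (!"sector_id" %in% names(records)) stop("`sector_id` column required")
  cols <- indicator_columns(records)
  X <- as.matrix(records[, cols, drop = FALSE])
  storage.mode(X) <- "integer"
  for (idx in split(seq_len(nrow(X)), records$sector_id)) {
    Xi <- X[idx, , drop = FALSE]
    if (!anyNA(Xi)) next
    M <- !is.na(Xi)
    A1 <- (Xi == 1L) & M
    A0 <- (Xi == 0L) & M
    rec <- which(rowSums(!M) > 0L & rowSums(M) > 0L)
    if (!length(rec)) next
    storage.mode(M) <- "double"
    storage.mode(A1) <- "double"
    storage.mode(A0) <- "double"
    joint <- M[rec, , drop = FALSE] %*% t(M)
    agree <- A1[rec, , drop = FALSE] %*% t(A1) + A0[rec, , drop = FALSE] %*% t(A0)
    elig <- joint > 0 & agree >= share_threshold * joint
    for (ri in seq_along(rec)) {
      i <- rec[ri]
      don_base <- elig[ri, ]
      don_base[i] <- FALSE # never one's own donor
      for (k in which(M[i, ] == 0)) {
        don <- don_base & M[, k] > 0
        if (any(don)) {
          n1 <- sum(A1[don, k])
          n0 <- sum(A0[don, k])
          X[idx[i], k] <- if (n1 >= n0) 1L else 0L
        }
      }
    }
  }
  records[, cols] <- as.data.frame(X)
  records
}

#' Sector-level prevalence of each deprivation indicator
#'
#' Prevalence is the share of observed values equal to 1 (deprived);
#' remaining missing values enter neither numerator nor denominator. Sectors
#' with no observed value for an indicator get `NA` prevalence and are
#' reported via the `"undefined"` attribute.
#'
#' @inheritParams impute_household
#' @return Data frame with one row per sector and indicator: `sector_id`,
#'   `indicator`, `prevalence`, `n_observed`, `n_persons`.
#' @export
compute_sector_prevalence <- function(records) {
  cols <- indicator_columns(records)
  DT <- as.data.table(records)
  long <- melt(
    DT[, c("sector_id", cols), with = FALSE],
    id.vars = "sector_id", variable.name = "indicator", value.name = "value",
    variable.factor = FALSE
  )
  long[, indicator := sub("^indicator_", "", indicator)]
  out <- long[, .(
    prevalence = if (sum(!is.na(value)) > 0) mean(value, na.rm = TRUE) else NA_real_,
    n_observed = sum(!is.na(value))
  ), by = .(sector_id, indicator)]
  np <- DT[, .(n_persons = .N), by = sector_id]
  out <- merge(out, np, by = "sector_id", sort = TRUE)
  undef <- out[n_observed == 0L, .(sector_id, indicator)]
  if (nrow(undef)) {
    message(nrow(undef), " sector-indicator cell(s) have no observed value; ",
            "prevalence undefined")
  }
  setDF(out)
  attr(out, "undefined") <- setDF(undef)
  out
}

#' Drop sectors at or below a minimum population
#'
#' Only sectors with strictly more than `min_inhabitants` inhabitants are
#' retained (the default reproduces the "more than 10 inhabitants" rule, so
#' a sector of exactly 10 is excluded). Excluded sectors are logged and
#' attached as the `"excluded"` attribute.
#'
#' @param prevalence Output of [compute_sector_prevalence()].
#' @param population Population table with `sector_id`, `count` and
#'   optionally `year` (the earliest year is used as the census snapshot).
#' @param min_inhabitants Exclusion threshold (strict).
#' @param year Optional census year overriding the default.
#' @return Filtered prevalence table, with excluded sectors as an attribute.
#' @export
filter_sectors <- function(prevalence, population, min_inhabitants = 10,
                           year = NULL) {
  tot <- sector_population_totals(population, year)
  pop <- tot$population[match(unique(prevalence$sector_id), tot$sector_id)]
  names(pop) <- unique(prevalence$sector_id)
  pop[is.na(pop)] <- 0
  small <- names(pop)[pop <= min_inhabitants]
  out <- prevalence[!prevalence$sector_id %in% small, , drop = FALSE]
  excluded <- data.frame(
    sector_id = small,
    population = unname(pop[small]),
    reason = rep(sprintf("population <= %d", as.integer(min_inhabitants)),
                 length(small)),
    stringsAsFactors = FALSE
  )
  if (nrow(excluded)) {
    message("excluded ", nrow(excluded), " sector(s) with <= ",
            min_inhabitants, " inhabitants")
  }
  attr(out, "excluded") <- excluded
  attr(out, "undefined") <- attr(prevalence, "undefined")
  out
}

#' Fit a maximum-likelihood factor model to sector prevalences
#'
#' Fits an ML factor model (via [stats::factanal()]) to the correlation
#' matrix of sector-level indicator prevalences, by default weighting
#' sectors by their number of persons, and computes sector scores by the
#' regression (Thomson) method. Scores are oriented so that higher score
#' means more deprived (positive correlation with mean indicator
#' prevalence). Sectors with any undefined prevalence are dropped and
#' recorded. A singular correlation matrix (e.g. perfectly collinear
#' indicators) falls back to principal-axis loadings and first-component
#' scores; a uniqueness at the optimizer's lower bound raises a Heywood-case
#' warning.
#'
#' @inheritParams filter_sectors
#' @param n_factors Number of factors; a deprivation index uses 1.
#' @param weights `"persons"` (person-weighted correlation, the default) or
#'   `"equal"`.
#' @return Object of class `"hdi_factor_model"`: loadings, uniquenesses,
#'   sector scores, the correlation matrix, and dropped sectors.
#' @export
fit_factor_model <- function(prevalence, n_factors = 1,
                             weights = c("persons", "equal")) {
  weights <- match.arg(weights)
  DT <- as.data.table(prevalence)
  wide <- dcast(DT, sector_id + n_persons ~ indicator, value.var = "prevalence")
  ind <- setdiff(names(wide), c("sector_id", "n_persons"))
  if (length(ind) < 3) stop("at least 3 indicators are required")
  cc <- stats::complete.cases(wide[, ind, with = FALSE])
  dropped <- wide$sector_id[!cc]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " sector(s) with undefined prevalence from the factor model")
  }
  wide <- wide[cc]
  if (nrow(wide) < 50) stop("at least 50 sectors are required to fit the factor model")
  P <- as.matrix(wide[, ind, with = FALSE])
  constant <- apply(P, 2, function(x) max(x) - min(x)) == 0
  if (any(constant)) {
    stop("indicator(s) with zero variance across sectors: ",
         paste(ind[constant], collapse = ", "))
  }
  w <- if (weights == "persons") wide$n_persons else rep(1, nrow(wide))
  cw <- cov.wt(P, wt = w / sum(w), cor = TRUE, method = "ML")
  R <- cw$cor
  dimnames(R) <- list(ind, ind)
  Z <- sweep(sweep(P, 2, cw$center), 2, sqrt(diag(cw$cov)), "/")

  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    # singular correlation matrix: principal-axis fallback
    warning("correlation matrix is singular; using principal-axis loadings")
    L <- ev$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(ev$values[seq_len(n_factors)]), n_factors)
    uniq <- pmax(1 - rowSums(L^2), 0.005)
    S <- Z %*% ev$vectors[, seq_len(n_factors), drop = FALSE]
    method <- "principal-axis (singular fallback)"
  } else {
    fa <- factanal(covmat = R, factors = n_factors, n.obs = nrow(P),
                   rotation = "none")
    L <- unclass(fa$loadings)
    uniq <- fa$uniquenesses
    if (any(uniq <= 0.005 + 1e-8)) {
      warning("Heywood case: uniqueness at lower bound for ",
              paste(ind[uniq <= 0.005 + 1e-8], collapse = ", "))
    }
    S <- Z %*% solve(R, L) # regression (Thomson) scores
    method <- "maximum likelihood"
  }
  rownames(L) <- ind
  names(uniq) <- ind
  # orient: deprivation score increases with mean indicator prevalence
  flip <- cor(S[, 1], rowMeans(Z))
  if (!is.na(flip) && flip < 0) {
    L[, 1] <- -L[, 1]
    S[, 1] <- -S[, 1]
  }
  structure(list(
    loadings = L,
    uniquenesses = uniq,
    scores = data.frame(sector_id = wide$sector_id, score = S[, 1],
                        stringsAsFactors = FALSE),
    score_matrix = S,
    correlation = R,
    n_factors = n_factors,
    n_obs = nrow(P),
    method = method,
    weights = weights,
    dropped_sectors = dropped
  ), class = "hdi_factor_model")
}

#' @export
print.hdi_factor_model <- function(x, ...) {
  cat("Housing deprivation factor model (", x$method, ")\n", sep = "")
  cat("  sectors:", x$n_obs, " factors:", x$n_factors, "\n")
  cat("  loadings (factor 1):\n")
  print(round(x$loadings[, 1], 3))
  invisible(x)
}

#' Rank sectors into deprivation deciles
#'
#' Sectors are sorted by descending deprivation score (ties broken by
#' sector id, a stable rule) and split into ten groups whose sizes differ
#' by at most one; decile 1 holds the most deprived tenth.
#'
#' @param model An `"hdi_factor_model"` or a data frame with `sector_id`
#'   and `score`.
#' @return Data frame with `sector_id`, `score`, `decile`, `excluded`,
#'   `exclusion_reason`.
#' @export
assign_deciles <- function(model) {
  scores <- if (inherits(model, "hdi_factor_model")) model$scores else model
  if (!all(c("sector_id", "score") %in% names(scores))) {
    stop("`model` must carry `sector_id` and `score`")
  }
  if (any(!is.finite(scores$score))) stop("non-finite scores present")
  n <- nrow(scores)
  if (n < 10) stop("at least 10 sectors are required to form deciles")
  ord <- order(-scores$score, scores$sector_id)
  dec <- integer(n)
  dec[ord] <- as.integer(floor((seq_len(n) - 1) * 10 / n)) + 1L
  data.frame(
    sector_id = scores$sector_id,
    score = scores$score,
    decile = dec,
    excluded = FALSE,
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Build the housing deprivation index end to end
#'
#' Chains household imputation, profile imputation, sector prevalences,
#' the small-sector filter, the ML factor model and decile assignment.
#' Sectors excluded for low population or undefined prevalence appear in
#' the assignment with `excluded = TRUE` and a reason.
#'
#' @param individuals Housing record table (see [generate_individuals()]
#'   for the schema).
#' @inheritParams filter_sectors
#' @inheritParams impute_profile
#' @inheritParams fit_factor_model
#' @return List with `assignment`, `model`, `prevalence`.
#' @export
build_deprivation_index <- function(individuals, population,
                                    min_inhabitants = 10,
                                    share_threshold = 0.75,
                                    n_factors = 1,
                                    weights = "persons") {
  rec <- impute_household(individuals)
  rec <- impute_profile(rec, share_threshold)
  prev <- compute_sector_prevalence(rec)
  prev_f <- filter_sectors(prev, population, min_inhabitants)
  model <- fit_factor_model(prev_f, n_factors = n_factors, weights = weights)
  asn <- assign_deciles(model)

  excl <- attr(prev_f, "excluded")
  excl_rows <- data.frame(
    sector_id = character(0), score = numeric(0), decile = integer(0),
    excluded = logical(0), exclusion_reason = character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(excl)) {
    excl_rows <- rbind(excl_rows, data.frame(
      sector_id = excl$sector_id, score = NA_real_, decile = NA_integer_,
      excluded = TRUE, exclusion_reason = excl$reason,
      stringsAsFactors = FALSE
    ))
  }
  if (length(model$dropped_sectors)) {
    excl_rows <- rbind(excl_rows, data.frame(
      sector_id = model$dropped_sectors, score = NA_real_,
      decile = NA_integer_, excluded = TRUE,
      exclusion_reason = "undefined prevalence after imputation",
      stringsAsFactors = FALSE
    ))
  }
  list(
    assignment = rbind(asn, excl_rows),
    model = model,
    prevalence = prev_f
  )
}
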