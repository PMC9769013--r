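test_that("household imputation copies the modal value and never overwrites", {
  rec <- make_records(rbind(
    c(1, 0), # A
    c(NA, 0), # B, same household as A
    c(NA, NA) # C, singleton household
  ), household = c("H1", "H1", "H2"))
  out <- impute_household(rec)
  expect_equal(out$indicator_1, c(1, 1, NA)) # single donor copied; no donor kept
  expect_equal(out$indicator_2, c(0, 0, NA))

  # tie between donor values resolves toward "deprived"
  rec2 <- make_records(rbind(c(1, 1), c(0, 1), c(NA, NA)),
                       household = c("H1", "H1", "H1"))
  out2 <- impute_household(rec2)
  expect_equal(out2$indicator_1[3], 1)
  expect_equal(out2$indicator_2[3], 1)

  # observed values never change, missing count never increases
  cfg <- tiny_config(n_sectors = 30, median_sector_pop = 40, seed = 3,
                     missing_rate = 0.2)
  ind <- inject_missingness(generate_individuals(generate_sectors(cfg), cfg), cfg)
  imp <- impute_household(ind)
  cols <- grep("^indicator_", names(ind), value = TRUE)
  for (cl in cols) {
    obs <- !is.na(ind[[cl]])
    expect_identical(imp[[cl]][obs], ind[[cl]][obs])
    expect_lte(sum(is.na(imp[[cl]])), sum(is.na(ind[[cl]])))
  }
})

test_that("profile imputation enforces the 75% agreement threshold", {
  # recipient shares 8/10 observed indicators with the only sector-mate
  recip <- c(rep(1, 10), NA)
  donor8 <- c(rep(1, 8), 0, 0, 1)
  rec <- make_records(rbind(recip, donor8))
  out <- impute_profile(rec, 0.75)
  expect_equal(out$indicator_11[1], 1) # 0.80 >= 0.75: donor eligible

  # 7/10 agreement is below the threshold: value stays missing
  donor7 <- c(rep(1, 7), 0, 0, 0, 1)
  out7 <- impute_profile(make_records(rbind(recip, donor7)), 0.75)
  expect_true(is.na(out7$indicator_11[1]))

  # a recipient with all indicators missing is untouched
  rec_all_na <- make_records(rbind(rep(NA, 4), c(1, 0, 1, 0)))
  out_na <- impute_profile(rec_all_na)
  expect_true(all(is.na(out_na[1, grep("^indicator_", names(out_na))])))

  # donors pooled across the sector, modal value with ties toward deprived
  rec3 <- make_records(rbind(
    c(1, 1, 1, NA),
    c(1, 1, 1, 1),
    c(1, 1, 1, 0)
  ))
  out3 <- impute_profile(rec3)
  expect_equal(out3$indicator_4[1], 1)

  expect_error(impute_profile(rec, share_threshold = 0), "share_threshold")
  expect_error(impute_profile(rec, share_threshold = 1.5), "share_threshold")
})

test_that("profile imputation uses pre-imputation donors only", {
  # B's value is filled from A; C disagrees with both on the jointly
  # observed indicators, so C must not receive B's freshly imputed value
  rec <- make_records(rbind(
    c(1, 1, 1, 1, 1),
    c(1, 1, 1, 1, NA),
    c(0, 0, 0, 0, NA)
  ))
  out <- impute_profile(rec)
  expect_equal(out$indicator_5[2], 1)
  expect_true(is.na(out$indicator_5[3]))
})

test_that("sector prevalence is the observed share of deprived values", {
  rec <- make_records(rbind(c(1), c(1), c(0), c(NA)))
  prev <- compute_sector_prevalence(rec)
  expect_equal(prev$prevalence, 2 / 3)
  expect_equal(prev$n_observed, 3L)
  expect_equal(prev$n_persons, 4L)

  rec0 <- make_records(matrix(0, nrow = 5, ncol = 2))
  expect_equal(compute_sector_prevalence(rec0)$prevalence, c(0, 0))

  # a sector with no observed value is flagged undefined
  recna <- rbind(make_records(rbind(c(NA, 1), c(NA, 0)), sector = "S1"),
                 make_records(rbind(c(1, 1)), sector = "S2"))
  expect_message(prevna <- compute_sector_prevalence(recna), "undefined")
  und <- attr(prevna, "undefined")
  expect_equal(und$sector_id, "S1")
  expect_equal(und$indicator, "1")
  expect_true(is.na(prevna$prevalence[prevna$sector_id == "S1" &
                                        prevna$indicator == "1"]))
})

test_that("the small-sector filter is strict at the threshold", {
  prev <- data.frame(
    sector_id = rep(c("S1", "S2", "S3"), each = 2),
    indicator = rep(c("a", "b"), 3),
    prevalence = 0.5, n_observed = 5L, n_persons = 5L
  )
  popn <- data.frame(
    sector_id = c("S1", "S2", "S3"),
    count = c(10L, 11L, 200L)
  )
  expect_message(out <- filter_sectors(prev, popn), "excluded 1 sector")
  expect_setequal(unique(out$sector_id), c("S2", "S3")) # 10 out, 11 in
  expect_equal(attr(out, "excluded")$sector_id, "S1")

  # no sector at or below the threshold: output equals input
  popn_big <- transform(popn, count = count + 100L)
  out2 <- filter_sectors(prev, popn_big)
  expect_equal(out2, prev, ignore_attr = TRUE)
  expect_equal(nrow(attr(out2, "excluded")), 0)
})

test_that("the ML factor model recovers loadings from an exact 1-factor matrix", {
  lambda <- c(0.8, 0.7, 0.6)
  R <- tcrossprod(lambda) + diag(1 - lambda^2)
  # build 200 'sectors' whose sample (ML) correlation matrix is exactly R
  set.seed(42)
  W <- matrix(rnorm(200 * 3), 200, 3)
  W <- scale(W, center = TRUE, scale = FALSE)
  S_ml <- crossprod(W) / nrow(W)
  Wh <- W %*% solve(chol(S_ml))
  X <- Wh %*% chol(R)
  X <- apply(X, 2, function(x) (x - min(x)) / (max(x) - min(x))) # into [0,1]
  prev <- data.frame(
    sector_id = rep(sprintf("S%03d", 1:200), each = 3),
    indicator = rep(c("a", "b", "c"), 200),
    prevalence = as.vector(t(X)),
    n_observed = 10L, n_persons = 10L
  )
  fm <- fit_factor_model(prev, weights = "equal")
  expect_lt(max(abs(abs(fm$loadings[, 1]) - lambda)), 0.01)
  expect_true(all(fm$uniquenesses > 0 & fm$uniquenesses <= 1))
  # orientation rule: score increases with mean prevalence
  wide <- matrix(prev$prevalence, ncol = 3, byrow = TRUE)
  expect_gt(cor(fm$scores$score, rowMeans(scale(wide))), 0)
})

test_that("identical indicator columns collapse to a prevalence ranking", {
  set.seed(7)
  p <- runif(80)
  prev <- data.frame(
    sector_id = rep(sprintf("S%03d", 1:80), each = 3),
    indicator = rep(c("a", "b", "c"), 80),
    prevalence = rep(p, each = 3),
    n_observed = 10L, n_persons = 10L
  )
  expect_warning(fm <- fit_factor_model(prev, weights = "equal"), "singular")
  expect_equal(order(fm$scores$score), order(p))
})

test_that("decile assignment is balanced, ordered and tie-stable", {
  sc <- data.frame(sector_id = sprintf("S%02d", 1:20),
                   score = seq(2, -2, length.out = 20))
  asn <- assign_deciles(sc)
  expect_equal(as.integer(table(asn$decile)), rep(2L, 10))
  expect_setequal(asn$sector_id[asn$decile == 1], c("S01", "S02"))

  # boundary ties resolved by sector id, partition still balanced
  sc_tie <- data.frame(sector_id = sprintf("S%02d", 1:20), score = 1)
  asn_tie <- assign_deciles(sc_tie)
  expect_equal(as.integer(table(asn_tie$decile)), rep(2L, 10))
  expect_equal(asn_tie$decile[asn_tie$sector_id == "S01"], 1L)
  expect_equal(asn_tie$decile[asn_tie$sector_id == "S20"], 10L)

  # orientation invariance: flipping all raw scores, then re-orienting,
  # yields the same deciles
  set.seed(1)
  sc2 <- data.frame(sector_id = sprintf("S%03d", 1:95), score = rnorm(95))
  a1 <- assign_deciles(sc2)
  expect_true(all(diff(range(table(a1$decile))) <= 1))

  expect_error(assign_deciles(sc[1:9, ]), "at least 10")
})

test_that("the index recovers a moderate synthetic gradient end to end", {
  cfg <- generator_config(n_sectors = 400, median_sector_pop = 120, seed = 17)
  sec <- generate_sectors(cfg)
  ind <- inject_missingness(generate_individuals(sec, cfg), cfg)
  pd <- generate_population_and_deaths(sec, config = cfg)
  idx <- build_deprivation_index(ind, pd$population)

  asn <- idx$assignment[!idx$assignment$excluded, ]
  m <- merge(asn, sec, by = "sector_id")
  expect_gt(cor(m$score, m$latent_deprivation, method = "spearman"), 0.7)
  # every retained sector in exactly one decile, sizes within 1
  expect_true(all(diff(range(table(asn$decile))) <= 1))
  expect_false(anyDuplicated(asn$sector_id) > 0)
})

test_that("imputation reduces but never manufactures missingness end to end", {
  cfg <- generator_config(n_sectors = 60, median_sector_pop = 100, seed = 23,
                          missing_rate = 0.12)
  sec <- generate_sectors(cfg)
  ind <- inject_missingness(generate_individuals(sec, cfg), cfg)
  cols <- grep("^indicator_", names(ind), value = TRUE)
  n0 <- sum(is.na(ind[cols]))
  h <- impute_household(ind)
  n1 <- sum(is.na(h[cols]))
  p <- impute_profile(h)
  n2 <- sum(is.na(p[cols]))
  expect_lte(n1, n0)
  expect_lte(n2, n1)
  expect_lt(n2, n0) # the two steps really do fill values
  for (cl in cols) {
    obs <- !is.na(ind[[cl]])
    expect_identical(p[[cl]][obs], ind[[cl]][obs])
  }
})
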