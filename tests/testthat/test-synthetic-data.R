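test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_sectors = 0), "positive")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  expect_error(generator_config(gompertz_a = 0), "gompertz_a")
  expect_error(generator_config(decile_rate_ratios = rep(1, 9)), "10")
  expect_error(generator_config(decile_rate_ratios = c(rep(1.2, 9), 1.1)),
               "reference")
  expect_error(generate_sectors(generator_config(n_sectors = 10)), "20")
})

test_that("sector generation matches the configured size distribution", {
  cfg <- generator_config(n_sectors = 1000, median_sector_pop = 300, seed = 1)
  s <- generate_sectors(cfg)
  expect_equal(nrow(s), 1000)
  expect_false(anyDuplicated(s$sector_id) > 0)
  expect_true(all(s$population_size >= 1))
  # realized median within 20% of the target
  expect_gt(median(s$population_size), 240)
  expect_lt(median(s$population_size), 360)

  # seeded determinism
  cfg2 <- generator_config(n_sectors = 20, median_sector_pop = 50, seed = 7)
  expect_identical(generate_sectors(cfg2), generate_sectors(cfg2))

  # latent deprivation is standard normal (CLT bound 3/sqrt(n))
  big <- generate_sectors(generator_config(n_sectors = 1e5,
                                           median_sector_pop = 5, seed = 3))
  expect_lt(abs(mean(big$latent_deprivation)), 0.02)
  expect_lt(abs(sd(big$latent_deprivation) - 1), 0.02)
})

test_that("individuals fill their sectors household by household", {
  cfg <- tiny_config(n_sectors = 50, median_sector_pop = 80, seed = 11)
  sec <- generate_sectors(cfg)
  ind <- generate_individuals(sec, cfg)
  # every sector exactly at its population, every person in one household
  got <- table(ind$sector_id)
  expect_equal(as.integer(got[sec$sector_id]), sec$population_size)
  expect_false(anyDuplicated(ind$person_id) > 0)
  hh_sec <- unique(ind[, c("household_id", "sector_id")])
  expect_false(anyDuplicated(hh_sec$household_id) > 0)
  # households average 2-3 members
  expect_gt(mean(table(ind$household_id)), 2)
  expect_lt(mean(table(ind$household_id)), 3)
  expect_error(generate_individuals(sec[0, ], cfg), "empty")
})

test_that("indicator prevalence follows the logistic link in the latent score", {
  # zero loading: prevalence independent of the latent score
  cfg0 <- generator_config(
    n_sectors = 400, median_sector_pop = 250, seed = 5,
    indicator_loadings = c(a = 0, b = 0, c = 0),
    indicator_intercepts = c(a = 0, b = -1, c = 1)
  )
  sec <- generate_sectors(cfg0)
  ind <- generate_individuals(sec, cfg0)
  prev <- tapply(ind$indicator_a, ind$sector_id, mean)
  expect_lt(abs(cor(prev[sec$sector_id], sec$latent_deprivation)), 0.12)
  # intercept 0, loading 0: prevalence 0.5 within 3 s.e.
  n <- nrow(ind)
  expect_lt(abs(mean(ind$indicator_a) - 0.5), 3 * sqrt(0.25 / n))

  # loading 1, intercept 0, latent +2 vs -2: prevalences at logistic(+-2)
  sec2 <- data.frame(
    sector_id = c("S1", "S2"), latent_deprivation = c(2, -2),
    population_size = c(40000L, 40000L)
  )
  cfg1 <- generator_config(
    n_sectors = 20, seed = 9,
    indicator_loadings = c(a = 1, b = 1, c = 1),
    indicator_intercepts = c(a = 0, b = 0, c = 0)
  )
  ind2 <- generate_individuals(sec2, cfg1)
  p_hi <- mean(ind2$indicator_a[ind2$sector_id == "S1"])
  p_lo <- mean(ind2$indicator_a[ind2$sector_id == "S2"])
  se <- sqrt(0.119 * 0.881 / 40000)
  expect_lt(abs(p_hi - plogis(2)), 3 * se)
  expect_lt(abs(p_lo - plogis(-2)), 3 * se)

  # positive loadings: sector prevalence increases with latent deprivation
  cfgp <- generator_config(n_sectors = 1000, median_sector_pop = 100, seed = 13)
  secp <- generate_sectors(cfgp)
  indp <- generate_individuals(secp, cfgp)
  prevp <- tapply(indp$indicator_tenant, indp$sector_id, mean)
  ct <- cor.test(prevp[secp$sector_id], secp$latent_deprivation,
                 method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.001)
})

test_that("missingness injection hits its target rate and preserves donors", {
  cfg <- generator_config(n_sectors = 80, median_sector_pop = 260, seed = 21,
                          missing_rate = 0.10)
  sec <- generate_sectors(cfg)
  ind <- generate_individuals(sec, cfg)

  # rate 0 is the identity
  cfg0 <- cfg; cfg0$missing_rate <- 0
  expect_identical(inject_missingness(ind, cfg0), ind)

  masked <- inject_missingness(ind, cfg)
  cols <- grep("^indicator_", names(ind), value = TRUE)
  vals <- unlist(masked[cols])
  expect_gte(length(vals), 1e5)
  frac <- mean(is.na(vals))
  expect_gt(frac, 0.094)
  expect_lt(frac, 0.106)
  # only masking, never un-masking or changing observed values
  for (cl in cols) {
    obs <- !is.na(masked[[cl]])
    expect_identical(masked[[cl]][obs], ind[[cl]][obs])
  }

  # without block masking, multi-person households always keep a donor
  cfgnb <- generator_config(n_sectors = 60, median_sector_pop = 150, seed = 22,
                            missing_rate = 0.4, block_missing_prob = 0)
  secnb <- generate_sectors(cfgnb)
  indnb <- generate_individuals(secnb, cfgnb)
  msknb <- inject_missingness(indnb, cfgnb)
  hh_n <- table(msknb$household_id)
  for (cl in grep("^indicator_", names(msknb), value = TRUE)) {
    n_obs <- tapply(!is.na(msknb[[cl]]), msknb$household_id, sum)
    multi <- names(hh_n)[hh_n >= 2]
    expect_true(all(n_obs[multi] >= 1))
  }

  cfg_bad <- cfg
  cfg_bad$missing_rate <- 1.2
  expect_error(inject_missingness(ind, cfg_bad), "missing_rate")
})

test_that("deaths follow the configured Gompertz-proportional mechanism", {
  cfg <- generator_config(
    n_sectors = 40, median_sector_pop = 4000, seed = 31,
    decile_rate_ratios = c(2, rep(1, 9)),
    periods = list(P1 = 2001:2010), period_factors = 1,
    male_hazard_ratio = 1
  )
  sec <- generate_sectors(cfg)
  pd <- generate_population_and_deaths(sec, config = cfg)

  # seeded determinism
  pd2 <- generate_population_and_deaths(sec, config = cfg)
  expect_identical(pd$deaths, pd2$deaths)
  expect_identical(pd$population, pd2$population)

  # realized age-specific rates within 3 Poisson s.e. of the hazard
  dec <- pd$ground_truth$deciles
  ref_sec <- dec$sector_id[dec$true_decile == 10]
  for (a in c(40, 60, 80)) {
    py <- sum(pd$population$count[pd$population$age == a &
                                    pd$population$sector_id %in% ref_sec])
    dth <- sum(pd$deaths$age_at_death == a &
                 pd$deaths$sector_id %in% ref_sec)
    lam <- py * cfg$gompertz_a * exp(cfg$gompertz_b * a)
    expect_lt(abs(dth - lam), 3 * sqrt(lam) + 1)
  }

  # all ratios 1 gives a null gradient
  cfg_null <- generator_config(n_sectors = 30, median_sector_pop = 50,
                               seed = 32, decile_rate_ratios = rep(1, 10))
  sec_null <- generate_sectors(cfg_null)
  pd_null <- generate_population_and_deaths(sec_null, config = cfg_null)
  expect_equal(pd_null$ground_truth$true_paf, 0)

  # unknown decile errors
  bad <- true_deciles(sec)
  bad$true_decile[1] <- NA
  expect_error(generate_population_and_deaths(sec, bad, cfg), "unknown decile")
})

test_that("the analytic ground-truth PAF matches brute-force enumeration", {
  # hand-checkable case: two effective deciles, one age class, equal PY
  # ratios (2, 1) imply PAF = (2 + 1 - 2) / (2 + 1) = 1/3
  lam_d <- c(2, 1) # expected deaths proportional to the ratios at equal PY
  expect_equal((sum(lam_d) - 2 * min(lam_d)) / sum(lam_d), 1 / 3)

  cfg <- generator_config(n_sectors = 50, median_sector_pop = 120, seed = 41,
                          decile_rate_ratios = seq(1.8, 1, length.out = 10))
  sec <- generate_sectors(cfg)
  dec <- true_deciles(sec)
  pd <- generate_population_and_deaths(sec, dec, cfg)

  # independent enumeration over every sector/sex/age/year stratum
  rr <- cfg$decile_rate_ratios
  pop <- pd$population
  d10 <- dec$true_decile[match(pop$sector_id, dec$sector_id)]
  yrs <- unlist(cfg$periods, use.names = FALSE)
  pf <- rep(cfg$period_factors, lengths(cfg$periods))[match(pop$year, yrs)]
  sexhr <- ifelse(pop$sex == "male", cfg$male_hazard_ratio, 1)
  lam <- pop$count * cfg$gompertz_a * exp(cfg$gompertz_b * pop$age) *
    sexhr * rr[d10] * pf
  lam_ref <- lam / rr[d10]
  paf_brute <- (sum(lam) - sum(lam_ref)) / sum(lam)
  expect_equal(pd$ground_truth$true_paf, paf_brute, tolerance = 1e-10)
})

test_that("ground-truth deciles partition sectors evenly, most deprived first", {
  sec <- data.frame(sector_id = sprintf("S%02d", 1:25),
                    latent_deprivation = rev(seq(-2, 2, length.out = 25)),
                    population_size = 10L)
  dec <- true_deciles(sec)
  expect_true(all(diff(range(table(dec$true_decile))) <= 1))
  expect_equal(dec$true_decile[which.max(sec$latent_deprivation)], 1L)
  expect_equal(dec$true_decile[which.min(sec$latent_deprivation)], 10L)
})
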