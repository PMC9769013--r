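#' Run the full deprivation-and-mortality pipeline on a synthetic registry
#'
#' Simulates a registry, builds the housing deprivation index, stratifies
#' mortality, and computes every inequality output: standardized rates and
#' their trends, Lorenz curves and Gini coefficients, attributable
#' fractions with Monte Carlo intervals, life tables for the extreme
#' deciles, the Arriaga decomposition, and PYLL. When `out_dir` is given,
#' every table is written as a CSV together with a JSON manifest (seed,
#' package version, row counts, file checksums).
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory.
#' @param seed Optional seed overriding `config$seed`.
#' @param n_reps Monte Carlo replicates for the attributable-fraction CI.
#' @param min_inhabitants Small-sector exclusion threshold (strict).
#' @param age_breaks Analysis age groups.
#' @param standard_year Year whose population defines the standard weights;
#'   default the latest simulated year.
#' @return Invisibly, a list with all intermediate and final tables.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, n_reps = 1000,
                         min_inhabitants = 10,
                         age_breaks = seq(0, 95, by = 5),
                         standard_year = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) config$seed <- 1L

  sim <- simulate_registry(config)
  index <- build_deprivation_index(sim$individuals, sim$population,
                                   min_inhabitants = min_inhabitants)
  strata <- stratify(sim$deaths, sim$population, index$assignment,
                     config$periods, age_breaks)
  standard <- standard_population(sim$population, year = standard_year,
                                  age_breaks = age_breaks)

  asmr <- direct_standardize(strata, standard)
  lorenz <- lorenz_points(strata, standard)
  gini_tab <- gini(lorenz)
  strata_exp <- expected_deaths(strata)
  paf <- paf_and_excess(strata_exp)
  paf_decile <- paf_and_excess(strata_exp, by = c("sex", "period", "decile"))
  paf_overall <- paf_and_excess(strata_exp, by = character(0))
  mc <- monte_carlo_ci(strata, n_reps = n_reps, seed = config$seed + 11L)
  mc_overall <- monte_carlo_ci(strata, n_reps = n_reps,
                               seed = config$seed + 12L, by = character(0))

  e0 <- life_expectancy_table(strata)
  dec_range <- range(strata$decile)
  sexes <- unique(strata$sex)
  periods <- names(config$periods)
  arriaga <- do.call(rbind, lapply(sexes, function(sx) {
    do.call(rbind, lapply(periods, function(pp) {
      dd <- arriaga_decompose(
        build_life_table(strata, sx, dec_range[1], pp),
        build_life_table(strata, sx, dec_range[2], pp)
      )
      cbind(sex = sx, period = pp, dd,
            delta_e0 = attr(dd, "delta_e0"))
    }))
  }))
  pyll_dec <- pyll_table(strata)
  py_w <- stats::aggregate(person_years ~ sex + period + decile,
                           data = strata, FUN = sum)
  names(py_w)[names(py_w) == "person_years"] <- "weight"
  pyll_ineq <- pyll_inequality(pyll_dec, weights = py_w)

  pfirst <- periods[1]
  plast <- periods[length(periods)]
  asmr_dt <- as.data.table(asmr)
  trends <- list(
    asmr = trend_table(
      asmr_dt[decile %in% dec_range,
              .(sex, extreme = ifelse(decile == dec_range[1], "most", "least"),
                period, value = rate)],
      metric = "rate", period_first = pfirst, period_last = plast
    ),
    e0 = trend_table(
      within(e0[e0$decile %in% dec_range, ], {
        extreme <- ifelse(decile == dec_range[1], "most", "least")
        value <- e0
      })[, c("sex", "extreme", "period", "value")],
      metric = "e0", period_first = pfirst, period_last = plast
    )
  )

  res <- list(
    sim = sim, index = index, strata = strata, standard = standard,
    asmr = asmr, asmr_trend = asmr_change(asmr, pfirst, plast),
    lorenz = lorenz, gini = gini_tab,
    strata_expected = strata_exp, paf = paf, paf_decile = paf_decile,
    paf_overall = paf_overall, mc = mc, mc_overall = mc_overall,
    e0 = e0, arriaga = arriaga,
    pyll = pyll_dec, pyll_inequality = pyll_ineq,
    trends = trends
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tabs <- list(
      hdi_scores = index$assignment,
      loadings = data.frame(indicator = rownames(index$model$loadings),
                            loading = index$model$loadings[, 1],
                            uniqueness = index$model$uniquenesses),
      strata = strata, standard_population = standard,
      asmr = asmr, lorenz = lorenz, gini = gini_tab,
      paf = mc, paf_decile = paf_decile,
      e0 = e0, arriaga = arriaga,
      pyll = pyll_ineq$by_decile, pyll_summary = pyll_ineq$summary
    )
    files <- character(0)
    for (nm in names(tabs)) {
      fp <- file.path(out_dir, paste0(nm, ".csv"))
      fwrite(as.data.frame(tabs[[nm]]), fp)
      files[nm] <- fp
    }
    manifest <- list(
      package = "housemort",
      version = as.character(utils::packageVersion("housemort")),
      seed = config$seed,
      n_sectors = config$n_sectors,
      n_individuals = nrow(sim$individuals),
      n_deaths = nrow(sim$deaths),
      dropped_deaths = as.list(attr(strata, "dropped")),
      excluded_sectors = sum(index$assignment$excluded),
      rows = lapply(tabs, nrow),
      md5 = as.list(tools::md5sum(unname(files)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}
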