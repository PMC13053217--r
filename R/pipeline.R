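# Config-driven orchestration of the full analysis: simulate (or load) ->
# STI -> CTI -> shift -> decomposition -> community statistics -> SST
# events and trends -> JSON report with provenance.

#' Default run configuration
#'
#' All thresholds default to the field values baked into the study design:
#' rare-species cover 5%, stress events 18 degC for 14 days, mortality
#' events 20 degC for 7 days, 0.1 degree climatology bins, 1 m depth bins,
#' 999 permutations, 2000 bootstrap resamples, June-August summer window
#' and a 1971-2000 anomaly baseline.
#'
#' @param seed integer seed; mandatory, consumed by every stochastic stage.
#' @return nested configuration list.
#' @export
default_config <- function(seed) {
  if (missing(seed)) stop("config requires a seed")
  list(
    seed = as.integer(seed),
    simulate = TRUE,
    paths = list(surveys = NULL, species = NULL, climatology = NULL,
                 sst_series = NULL),
    thresholds = list(rare_species = 0.05,
                      stress_c = 18, stress_days = 14,
                      mortality_c = 20, mortality_days = 7),
    bins = list(climatology_deg = 0.1, depth_m = 1),
    n_perm = 999, n_boot = 2000,
    season_months = 6:8,
    baseline_years = c(1971, 2000),
    bin_weighting = "equal")
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file; keys as in [default_config()]. A `seed` entry is
#'   required.
#' @return configuration list (defaults filled in for missing keys).
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(user$seed)) stop("config file must specify a seed")
  cfg <- default_config(seed = user$seed)
  for (k in setdiff(names(user), "seed")) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages: acquire inputs (simulate with ground-truth ledgers, or read the
#' CSV tables named in `config$paths`), compute STIs and affinities, CTI
#' per quadrat, the bootstrap CTI shift, the four-process decomposition,
#' PERMANOVA / dispersion / SIMPER community statistics, and SST
#' event/trend statistics. Deterministic given (config, seed). A stage
#' failure aborts with the stage name and cause.
#'
#' @param config list from [default_config()] or [read_config()].
#' @param out_json optional path; when given, the report is written there
#'   as JSON (with a provenance block holding the config hash and stage
#'   order) and removed again if any later stage fails.
#' @return report list (invisibly when `out_json` is given).
#' @export
run_pipeline <- function(config, out_json = NULL) {
  if (is.null(config$seed)) stop("config requires a seed")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_json) && file.exists(out_json)) unlink(out_json)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stages <- c("inputs", "sti", "cti", "shift", "decompose", "community",
              "events", "trends")

  inputs <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      world <- gen_paired_surveys(community_scenario(seed = config$seed))
      sstw <- gen_sst_series(sst_scenario(
        trend_per_decade = 0.33,
        events = data.frame(year = c(1977, 1998, 2016),
                            start_doy = c(190, 195, 200),
                            length = c(16, 14, 21),
                            level = c(20.5, 18.4, 19.2)),
        seed = config$seed + 1L))
      list(pairs = world$pairs, species = world$species,
           climatology = world$climatology, series = sstw$series,
           ledger = list(community = world$ledger, sst = sstw$ledger))
    } else {
      surveys <- read_surveys(config$paths$surveys)
      pairs <- filter_quadrats(pair_surveys(surveys)$pairs)$retained
      species <- read_species_metadata(config$paths$species)
      clim <- as_climatology(
        utils::read.csv(config$paths$climatology),
        bin_width = config$bins$climatology_deg)
      series <- read_sst_series(config$paths$sst_series)
      list(pairs = pairs, species = species, climatology = clim,
           series = series, ledger = NULL)
    }
  })

  sti_tab <- stage("sti", {
    keep <- rare_species_filter(inputs$pairs,
                                threshold = config$thresholds$rare_species)
    recs <- inputs$species[intersect(names(inputs$species), keep)]
    if (length(recs) == 0) stop("no species pass the rare-species filter")
    tab <- compute_sti_table(recs, inputs$climatology)
    historical <- unique(unlist(lapply(inputs$pairs, function(p)
      names(p$historical$cover)[p$historical$cover > 0])))
    classify_affinity(tab, intersect(historical, tab$species))
  })

  cti_tab <- stage("cti", cti_table(inputs$pairs, sti_tab))

  shift <- stage("shift", estimate_cti_shift(
    cti_tab, method = "paired_bootstrap",
    n_boot = config$n_boot, seed = config$seed + 2L))

  decomp <- stage("decompose", decompose_cti_change(
    inputs$pairs, sti_tab, bin_width = config$bins$depth_m,
    bin_weighting = config$bin_weighting))

  community <- stage("community", {
    cm <- community_matrix(inputs$pairs, species = sti_tab$species)
    dm <- bray_curtis_matrix(cm$x)
    list(permanova = permanova(dm, cm$groups, n_perm = config$n_perm,
                               seed = config$seed + 3L),
         dispersion = dispersion_homogeneity(dm, cm$groups),
         simper = simper(cm$x, cm$groups))
  })

  events <- stage("events", {
    th <- config$thresholds
    list(stress = detect_events(inputs$series, th$stress_c, th$stress_days,
                                kind = "stress"),
         mortality = detect_events(inputs$series, th$mortality_c,
                                   th$mortality_days, kind = "mortality"),
         days_18 = days_above(inputs$series, th$stress_c,
                              months = config$season_months),
         days_20 = days_above(inputs$series, th$mortality_c,
                              months = config$season_months))
  })

  trends <- stage("trends", {
    summer <- annual_means(inputs$series, "summer")
    d18 <- events$days_18
    ev_years <- d18$year[!is.na(d18$n_days)]
    stress_in_year <- vapply(ev_years, function(y)
      any(format(events$stress$start_date, "%Y") == as.character(y)), TRUE)
    mk <- mann_kendall(d18$n_days, d18$year)
    list(summer_rate = trend_rate(summer, n_boot = min(config$n_boot, 500),
                                  seed = config$seed + 4L),
         days18_mk = list(tau = mk$tau, s = mk$s, p_value = mk$p_value,
                          n = mk$n),
         days18_sen = sen_slope(d18$n_days, d18$year),
         stress_odds = if (length(unique(stress_in_year)) == 2)
           event_odds_trend(stress_in_year, ev_years) else NULL)
  })

  report <- list(
    provenance = list(package = "deboreal",
                      version = as.character(utils::packageVersion("deboreal")),
                      config_hash = .config_hash(config),
                      stage_order = stages,
                      seed = config$seed),
    cti_shift = unclass(shift),
    decomposition = list(proportions = as.list(decomp$proportions),
                         no_change = decomp$no_change,
                         dominant = if (decomp$no_change) NULL
                         else dominant_process(decomp)),
    community = list(
      permanova = unclass(community$permanova),
      dispersion = unclass(community$dispersion)[c("statistic", "p_value")],
      simper_top = utils::head(community$simper, 10),
      mean_dissimilarity = attr(community$simper, "mean_dissimilarity")),
    events = list(n_stress = nrow(events$stress),
                  n_mortality = nrow(events$mortality)),
    trends = trends,
    ledger = inputs$ledger)
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = 12,
                         na = "null", force = TRUE)
    return(invisible(report))
  }
  report
}
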