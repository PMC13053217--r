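# Synthetic-data generators with known ground truth: latitudinal SST
# climatologies with species ranges carrying closed-form STIs, paired
# quadrat communities with a controllable CTI shift or process mix, and
# daily SST series with trend, seasonality, AR(1) noise and injected heat
# events. Every generator is bit-reproducible given its scenario and seed.

#' Climatology scenario and generator
#'
#' Generates a latitude-binned coastal SST climatology following a linear
#' (monotone decreasing poleward) gradient, optionally with Gaussian noise
#' per bin, plus species latitudinal ranges whose noiseless STIs are known
#' in closed form. Defaults emulate the eastern Pacific coastal gradient
#' from Central America to the Gulf of Alaska: about 28 degC at 5 N
#' falling to about 5.6 degC at 61 N.
#'
#' Cold-affinity species get high-latitude ranges and warm-affinity species
#' low-latitude ranges, so the two classes have well-separated STIs.
#'
#' @param n_cold,n_warm numbers of cold- and warm-affinity species.
#' @param lat_range coastline extent in degrees latitude.
#' @param bin_width climatology bin width in degrees.
#' @param sst_intercept,sst_slope gradient `sst = intercept - slope * lat`.
#' @param noise_sd per-bin Gaussian noise standard deviation (0 = exact
#'   gradient).
#' @param seed integer seed (mandatory).
#' @return list with `climatology` (a `climatology`), `species` (list of
#'   `species_record`), and `expected_sti` (named vector of closed-form
#'   noiseless STIs).
#' @export
gen_climatology <- function(n_cold = 8, n_warm = 4, lat_range = c(5, 61),
                            bin_width = 0.1, sst_intercept = 30,
                            sst_slope = 0.4, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(sst_slope > 0, lat_range[1] < lat_range[2])
  set.seed(as.integer(seed))
  centers <- seq(ceiling(lat_range[1] / bin_width) * bin_width,
                 floor(lat_range[2] / bin_width) * bin_width,
                 by = bin_width)
  centers <- round(centers, 9)
  sst <- sst_intercept - sst_slope * centers
  if (noise_sd > 0) sst <- sst + stats::rnorm(length(sst), 0, noise_sd)
  clim <- as_climatology(data.frame(lat_center = centers, mean_sst = sst),
                         bin_width = bin_width)

  range_for <- function(center, half_span) {
    lo <- max(lat_range[1], center - half_span)
    hi <- min(lat_range[2], center + half_span)
    c(lo, hi)
  }
  # cold species centered 48-58 N, warm species 20-30 N; with the default
  # gradient the classes' STI intervals ([7.8, 10.8] and [18, 22] degC) are
  # separated by any historical-community baseline whenever n_cold >= 1 and
  # n_warm < 2.5 * n_cold, so generator roles always match classify_affinity
  mk_species <- function(i, affinity) {
    center <- if (affinity == "cold") stats::runif(1, 48, 58)
              else stats::runif(1, 20, 30)
    span <- stats::runif(1, 2, 8)
    r <- range_for(center, span)
    species_record(sprintf("%s_sp_%02d", affinity, i),
                   functional_group = if (affinity == "cold") "kelp" else "red_blade",
                   lat_min = r[1], lat_max = r[2])
  }
  species <- c(lapply(seq_len(n_cold), mk_species, affinity = "cold"),
               lapply(seq_len(n_warm), mk_species, affinity = "warm"))
  names(species) <- vapply(species, `[[`, "", "name")
  # closed form: the noiseless line averaged over included bin centers is
  # the line evaluated at the mean of the first and last included center
  expected_sti <- vapply(species, function(sp) {
    inc <- centers[centers >= sp$lat_min & centers <= sp$lat_max]
    sst_intercept - sst_slope * (inc[1] + inc[length(inc)]) / 2
  }, 0)
  list(climatology = clim, species = species, expected_sti = expected_sti)
}

#' Community scenario for paired-quadrat generation
#'
#' The stated world mirrors the study design: 48 paired quadrats surveyed
#' at two timepoints half a century apart, depths 0-8 m below chart datum,
#' a community of mostly cold-affinity species with a few warm-affinity
#' ones, and a logistic depth taper that concentrates cover in the
#' shallows (emulating the shallow bias of the historical sampling).
#'
#' Two modes control the ground truth:
#' \describe{
#'   \item{`process_mix`}{every species gets a fixed signed cover change
#'     applied identically in all quadrats, allocated so the depth-binned
#'     decomposition equals `target_mix` exactly.}
#'   \item{`cti_shift`}{per quadrat, a target CTI change is drawn from
#'     `N(delta_cti_mean, delta_cti_sd)` and realized exactly by rescaling
#'     cold-species cover, so the mean CTI shift over quadrats estimates
#'     `delta_cti_mean`.}
#' }
#'
#' @param n_quadrats number of paired quadrats.
#' @param depth_range survey depth range in meters below chart datum.
#' @param n_cold,n_warm species-pool sizes by affinity class.
#' @param mean_cover target mean of the Beta cover draw before scaling.
#' @param overdispersion Beta concentration (larger = less spread).
#' @param mode `"cti_shift"` (default) or `"process_mix"`.
#' @param delta_cti_mean,delta_cti_sd per-quadrat CTI-change distribution
#'   (degC), `cti_shift` mode.
#' @param target_mix named fractions over
#'   `c("tropicalization", "deborealization", "borealization",
#'   "detropicalization")` summing to 1 (or all zero for a no-change
#'   world), `process_mix` mode.
#' @param total_abs_change total absolute cover change budget distributed
#'   across species, `process_mix` mode.
#' @param taper_midpoint_m,taper_scale_m logistic depth-taper parameters.
#' @param seed integer seed (mandatory).
#' @return a `community_scenario` list.
#' @export
community_scenario <- function(n_quadrats = 48, depth_range = c(0, 8),
                               n_cold = 8, n_warm = 4,
                               mean_cover = 0.35, overdispersion = 30,
                               mode = c("cti_shift", "process_mix"),
                               delta_cti_mean = 1.4, delta_cti_sd = 0.8,
                               target_mix = c(tropicalization = 0.1,
                                              deborealization = 0.8,
                                              borealization = 0.05,
                                              detropicalization = 0.05),
                               total_abs_change = 0.5,
                               taper_midpoint_m = 5, taper_scale_m = 2,
                               seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  procs <- c("tropicalization", "deborealization", "borealization",
             "detropicalization")
  target_mix <- target_mix[procs]
  names(target_mix) <- procs
  target_mix[is.na(target_mix)] <- 0
  if (mode == "process_mix") {
    s <- sum(target_mix)
    if (s > 0 && abs(s - 1) > 1e-9) stop("target_mix must sum to 1 (or all zero)")
    if ((target_mix["tropicalization"] > 0 || target_mix["detropicalization"] > 0) &&
        n_warm == 0)
      stop("warm-species processes requested with n_warm = 0")
    if ((target_mix["borealization"] > 0 || target_mix["deborealization"] > 0) &&
        n_cold == 0)
      stop("cold-species processes requested with n_cold = 0")
  }
  structure(list(n_quadrats = n_quadrats, depth_range = depth_range,
                 n_cold = n_cold, n_warm = n_warm, mean_cover = mean_cover,
                 overdispersion = overdispersion, mode = mode,
                 delta_cti_mean = delta_cti_mean, delta_cti_sd = delta_cti_sd,
                 target_mix = target_mix, total_abs_change = total_abs_change,
                 taper_midpoint_m = taper_midpoint_m,
                 taper_scale_m = taper_scale_m, seed = as.integer(seed)),
            class = "community_scenario")
}

#' Generate paired quadrat surveys with known ground truth
#'
#' See [community_scenario()] for the two generation modes. The returned
#' ledger records the generator's own arithmetic for the true mean CTI
#' change and (in `process_mix` mode) the exact expected process mix, so
#' pipeline estimates can be checked against an independent ground truth.
#'
#' @param scenario a `community_scenario`.
#' @return list with `pairs` (list of `paired_quadrat`), `climatology`,
#'   `species`, `sti_table` (with affinity classified against the
#'   historical community), and `ledger` (list: `true_delta_cti`,
#'   `realized_delta_cti`, `per_quadrat_delta`, `true_mix`,
#'   `species_delta`).
#' @export
gen_paired_surveys <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  world <- gen_climatology(n_cold = sc$n_cold, n_warm = sc$n_warm,
                           seed = sc$seed + 1L)
  sti <- world$expected_sti
  affinity_class <- rep(c("cold", "warm"), c(sc$n_cold, sc$n_warm))
  names(affinity_class) <- names(world$species)
  sp_names <- names(world$species)
  n_sp <- length(sp_names)

  # per-species fixed cover change (process_mix mode)
  delta_sp <- stats::setNames(numeric(n_sp), sp_names)
  if (sc$mode == "process_mix" && sum(sc$target_mix) > 0) {
    role_of <- list(tropicalization = c("warm", +1),
                    deborealization = c("cold", -1),
                    borealization = c("cold", +1),
                    detropicalization = c("warm", -1))
    cold_idx <- sp_names[affinity_class == "cold"]
    warm_idx <- sp_names[affinity_class == "warm"]
    # round-robin species assignment per class over the active processes
    active <- names(sc$target_mix)[sc$target_mix > 0]
    cold_procs <- intersect(active, c("deborealization", "borealization"))
    warm_procs <- intersect(active, c("tropicalization", "detropicalization"))
    assign_class <- function(pool, pr) {
      if (length(pr) == 0) return(list())
      split(pool, rep(pr, length.out = length(pool)))
    }
    groups <- c(assign_class(cold_idx, cold_procs),
                assign_class(warm_idx, warm_procs))
    for (p in active) {
      members <- groups[[p]]
      if (is.null(members) || length(members) == 0)
        stop("infeasible mix: no species available for ", p)
      sgn <- as.numeric(role_of[[p]][2])
      delta_sp[members] <- sgn * sc$target_mix[[p]] *
        sc$total_abs_change / length(members)
    }
  }

  taper <- function(depth) 1 / (1 + exp((depth - sc$taper_midpoint_m) /
                                          sc$taper_scale_m))
  a <- sc$mean_cover * sc$overdispersion
  b <- (1 - sc$mean_cover) * sc$overdispersion

  pairs <- vector("list", sc$n_quadrats)
  realized_delta <- numeric(sc$n_quadrats)
  depths <- stats::runif(sc$n_quadrats, sc$depth_range[1], sc$depth_range[2])
  for (q in seq_len(sc$n_quadrats)) {
    tp <- taper(depths[q])
    base <- stats::rbeta(n_sp, a, b) * tp
    # keep head-room for the deterministic per-species change
    hist_cover <- ifelse(delta_sp < 0, abs(delta_sp) + (1 - abs(delta_sp)) * base,
                         (1 - delta_sp) * base)
    names(hist_cover) <- sp_names
    if (sc$mode == "process_mix") {
      mod_cover <- hist_cover + delta_sp
    } else {
      # realize an exact per-quadrat CTI change by rescaling cold cover
      d_target <- stats::rnorm(1, sc$delta_cti_mean, sc$delta_cti_sd)
      cold <- affinity_class == "cold"
      A_c <- sum(hist_cover[cold] * sti[cold]); W_c <- sum(hist_cover[cold])
      A_w <- sum(hist_cover[!cold] * sti[!cold]); W_w <- sum(hist_cover[!cold])
      cti_hist <- (A_c + A_w) / (W_c + W_w)
      q_max <- if (any(cold)) 1 / max(hist_cover[cold]) else 1
      cti_of <- function(qq) (qq * A_c + A_w) / (qq * W_c + W_w)
      # CTI is decreasing in the cold multiplier: clamp target to feasibility
      t_lo <- cti_of(q_max) + 1e-9; t_hi <- cti_of(0) - 1e-9
      target_cti <- min(max(cti_hist + d_target, t_lo), t_hi)
      qq <- (A_w - target_cti * W_w) / (target_cti * W_c - A_c)
      mod_cover <- hist_cover
      mod_cover[cold] <- qq * hist_cover[cold]
    }
    mod_cover <- pmin(pmax(mod_cover, 0), 1)
    cti_of_cover <- function(cv) sum(cv * sti) / sum(cv)
    realized_delta[q] <- cti_of_cover(mod_cover) - cti_of_cover(hist_cover)
    id <- sprintf("Q%03d", q)
    pairs[[q]] <- paired_quadrat(
      quadrat_survey(id, transect_id = sprintf("T%02d", 1 + (q - 1) %/% 6),
                     year = 1972L, depth_m = depths[q],
                     substrate = c("bedrock", "boulder"),
                     cover = hist_cover),
      quadrat_survey(id, transect_id = sprintf("T%02d", 1 + (q - 1) %/% 6),
                     year = 2023L, depth_m = depths[q],
                     substrate = c("bedrock", "boulder"),
                     cover = mod_cover))
  }

  sti_table <- data.frame(species = sp_names, sti = unname(sti),
                          affinity = NA_character_, stringsAsFactors = FALSE)
  sti_table <- classify_affinity(sti_table, sp_names)
  ledger <- list(
    true_delta_cti = if (sc$mode == "cti_shift") sc$delta_cti_mean else NA_real_,
    realized_delta_cti = mean(realized_delta),
    per_quadrat_delta = realized_delta,
    true_mix = if (sc$mode == "process_mix") sc$target_mix else NULL,
    species_delta = delta_sp,
    affinity_class = affinity_class)
  list(pairs = pairs, climatology = world$climatology,
       species = world$species, sti_table = sti_table, ledger = ledger)
}

#' Daily-SST scenario
#'
#' Defaults emulate a six-decade temperate coastal lighthouse record:
#' seasonal sinusoid peaking around the start of August with the summer
#' maximum just below the 18 degC stress threshold, mild AR(1) day-to-day
#' noise, an optional linear warming trend, and injected exceedance blocks
#' with known dates.
#'
#' @param years length-2 inclusive calendar-year range.
#' @param mean_sst annual mean SST, degC.
#' @param seasonal_amplitude half peak-to-trough seasonal range, degC.
#' @param peak_doy day-of-year of the seasonal maximum.
#' @param trend_per_decade linear trend, degC per decade.
#' @param ar1 AR(1) coefficient of the daily noise, in (-1, 1).
#' @param innovation_sd AR(1) innovation standard deviation (0 = noiseless).
#' @param events data frame of injected blocks with columns `year`,
#'   `start_doy`, `length`, `level`; blocks must not overlap.
#' @param gap_years integer years to drop entirely (emulating missing
#'   records).
#' @param seed integer seed (mandatory).
#' @return an `sst_scenario` list.
#' @export
sst_scenario <- function(years = c(1962, 2023), mean_sst = 12,
                         seasonal_amplitude = 5, peak_doy = 213,
                         trend_per_decade = 0, ar1 = 0.6,
                         innovation_sd = 0.35,
                         events = NULL, gap_years = integer(0), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(ar1) < 1, innovation_sd >= 0)
  if (!is.null(events)) {
    stopifnot(all(c("year", "start_doy", "length", "level") %in% names(events)))
  }
  structure(list(years = years, mean_sst = mean_sst,
                 seasonal_amplitude = seasonal_amplitude, peak_doy = peak_doy,
                 trend_per_decade = trend_per_decade, ar1 = ar1,
                 innovation_sd = innovation_sd, events = events,
                 gap_years = as.integer(gap_years), seed = as.integer(seed)),
            class = "sst_scenario")
}

#' Generate a daily SST series with known injected events
#'
#' @param scenario an `sst_scenario`.
#' @return list with `series` (a `daily_sst`) and `ledger`: data frame of
#'   injected events (`start_date`, `end_date`, `length`, `level`,
#'   `qualifies_stress`, `qualifies_mortality`) plus attributes; plus
#'   `true_trend_per_decade`.
#' @export
gen_sst_series <- function(scenario) {
  stopifnot(inherits(scenario, "sst_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  dates <- seq(as.Date(sprintf("%d-01-01", sc$years[1])),
               as.Date(sprintf("%d-12-31", sc$years[2])), by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr_frac <- as.numeric(dates - dates[1]) / 365.25
  sst <- sc$mean_sst +
    sc$seasonal_amplitude * cos(2 * pi * (doy - sc$peak_doy) / 365.25) +
    sc$trend_per_decade / 10 * yr_frac
  if (sc$innovation_sd > 0) {
    e <- stats::rnorm(length(dates), 0, sc$innovation_sd)
    noise <- stats::filter(e, sc$ar1, method = "recursive")
    sst <- sst + as.numeric(noise)
  }
  ledger_rows <- list()
  if (!is.null(sc$events) && nrow(sc$events) > 0) {
    occupied <- rep(FALSE, length(dates))
    for (k in seq_len(nrow(sc$events))) {
      ev <- sc$events[k, ]
      start <- as.Date(sprintf("%d-01-01", ev$year)) + (ev$start_doy - 1)
      idx <- which(dates >= start & dates < start + ev$length)
      if (length(idx) != ev$length) stop("injected event outside series range")
      if (any(occupied[idx])) stop("injected events overlap")
      occupied[idx] <- TRUE
      sst[idx] <- ev$level
      ledger_rows[[k]] <- data.frame(
        start_date = start, end_date = start + ev$length - 1,
        length = as.integer(ev$length), level = ev$level,
        qualifies_stress = ev$length >= 14 && ev$level >= 18,
        qualifies_mortality = ev$length >= 7 && ev$level >= 20)
    }
  }
  keep <- !(as.integer(format(dates, "%Y")) %in% sc$gap_years)
  series <- daily_sst_series(dates[keep], sst[keep])
  ledger <- if (length(ledger_rows)) do.call(rbind, ledger_rows) else
    data.frame(start_date = as.Date(character(0)),
               end_date = as.Date(character(0)),
               length = integer(0), level = numeric(0),
               qualifies_stress = logical(0), qualifies_mortality = logical(0))
  list(series = series, ledger = ledger,
       true_trend_per_decade = sc$trend_per_decade)
}
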