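# Daily-SST extreme-event detection and trend statistics: threshold-day
# counts, maximal-run event detection, Mann-Kendall/Sen trend tests,
# logistic event-frequency odds, smoothing-based decadal warming rates, and
# baseline anomalies with Pearson correlation.

#' Construct a daily SST series
#'
#' @param dates `Date` vector, strictly increasing (gaps allowed; they break
#'   event runs).
#' @param sst numeric SST in degrees Celsius.
#' @param psu optional salinity.
#' @return data frame of class `daily_sst` with columns `date`, `sst` and
#'   optionally `psu`.
#' @export
daily_sst_series <- function(dates, sst, psu = NULL) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(sst))
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be strictly increasing (unique calendar days)")
  out <- data.frame(date = dates, sst = as.numeric(sst))
  if (!is.null(psu)) out$psu <- as.numeric(psu)
  class(out) <- c("daily_sst", "data.frame")
  out
}

#' Read a daily SST/salinity series from CSV
#'
#' @param path CSV with ISO-8601 `date`, `sst_c` and optional `psu` columns.
#' @return `daily_sst` data frame.
#' @export
read_sst_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "sst_c")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  daily_sst_series(as.Date(df$date), df$sst_c,
                   psu = if ("psu" %in% names(df)) df$psu else NULL)
}

#' Annual counts of days at or above a temperature threshold
#'
#' Counts, for each calendar year spanned by the series, the days inside a
#' seasonal window (default June-August, the bull-kelp stress season) with
#' SST at or above `threshold`. Years with no observations in their window
#' are reported as `NA`, not zero, so data gaps are visible.
#'
#' @param series `daily_sst` data frame.
#' @param threshold temperature threshold in degrees Celsius (comparison is
#'   `>=`).
#' @param months integer months defining the seasonal window; `NULL` for
#'   the whole year.
#' @return data frame with `year` and `n_days`.
#' @export
days_above <- function(series, threshold, months = 6:8) {
  if (nrow(series) == 0) stop("empty series")
  stopifnot(is.finite(threshold))
  yr <- as.integer(format(series$date, "%Y"))
  mo <- as.integer(format(series$date, "%m"))
  in_window <- if (is.null(months)) rep(TRUE, nrow(series)) else mo %in% months
  years <- seq(min(yr), max(yr))
  n_days <- vapply(years, function(y) {
    sel <- yr == y & in_window
    if (!any(sel)) return(NA_integer_)
    sum(series$sst[sel] >= threshold)
  }, 0L)
  data.frame(year = years, n_days = n_days)
}

#' Detect maximal threshold-exceedance heat events
#'
#' An event is a maximal run of consecutive calendar days with SST at or
#' above `threshold` lasting at least `min_days`. A missing day breaks a
#' run (conservative given gappy lighthouse records). The field defaults
#' are a "stress" event (>= 18 degC for >= 14 days, two weeks of
#' physiological stress for bull kelp) and a "mortality" /
#' reproductive-failure event (>= 20 degC for >= 7 days).
#'
#' @param series `daily_sst` data frame.
#' @param threshold temperature threshold in degrees Celsius.
#' @param min_days minimum run length in days (inclusive count).
#' @param kind label attached to the events (e.g. `"stress"`,
#'   `"mortality"`).
#' @return data frame with `start_date`, `end_date`, `length`, `threshold`,
#'   `kind`; zero rows when no event qualifies.
#' @export
detect_events <- function(series, threshold, min_days, kind = "event") {
  stopifnot(min_days >= 1)
  hot <- series$sst >= threshold
  n <- nrow(series)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (hot[i]) {
      j <- i
      while (j < n && hot[j + 1L] &&
             as.integer(series$date[j + 1L] - series$date[j]) == 1L) {
        j <- j + 1L
      }
      len <- as.integer(series$date[j] - series$date[i]) + 1L
      if (len >= min_days) { starts <- c(starts, i); ends <- c(ends, j) }
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start_date = series$date[starts],
             end_date = series$date[ends],
             length = as.integer(series$date[ends] - series$date[starts]) + 1L,
             threshold = rep(threshold, length(starts)),
             kind = rep(kind, length(starts)),
             stringsAsFactors = FALSE)
}

#' Detect stress events (>= 18 degC for >= 14 consecutive days)
#' @param series `daily_sst` data frame.
#' @param threshold,min_days override the field defaults.
#' @return see [detect_events()].
#' @export
detect_stress_events <- function(series, threshold = 18, min_days = 14)
  detect_events(series, threshold, min_days, kind = "stress")

#' Detect mortality events (>= 20 degC for >= 7 consecutive days)
#' @param series `daily_sst` data frame.
#' @param threshold,min_days override the field defaults.
#' @return see [detect_events()].
#' @export
detect_mortality_events <- function(series, threshold = 20, min_days = 7)
  detect_events(series, threshold, min_days, kind = "mortality")

#' Mann-Kendall trend test
#'
#' Computes `S = sum_{i<j} sign(v_j - v_i)` over the time-ordered values,
#' the tie-corrected variance, a normal approximation with continuity
#' correction for the two-sided p-value, and the tie-corrected tau-b.
#' Missing values are dropped together with their years.
#'
#' @param values numeric series (annual counts, means, ...).
#' @param years time index (default `seq_along(values)`); must be strictly
#'   increasing after NA removal.
#' @return object of class `trend_result`: list with `tau`, `s`, `p_value`,
#'   `n`.
#' @export
mann_kendall <- function(values, years = seq_along(values)) {
  ok <- is.finite(values)
  v <- values[ok]; t <- years[ok]
  n <- length(v)
  if (n < 4) stop("need at least 4 non-missing values")
  if (is.unsorted(t, strictly = TRUE)) stop("years must be strictly increasing")
  s <- 0
  for (i in seq_len(n - 1)) s <- s + sum(sign(v[(i + 1):n] - v[i]))
  ties <- table(v)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  n0 <- n * (n - 1) / 2
  tie_term <- sum(ties * (ties - 1) / 2)
  denom <- sqrt((n0 - tie_term) * n0)  # times strictly increasing: no time ties
  tau <- if (denom > 0) s / denom else 0
  if (var_s <= 0 || s == 0) {
    p <- if (s == 0) 1 else NA_real_
  } else {
    z <- (s - sign(s)) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(tau = tau, s = s, p_value = p, n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Mann-Kendall: tau = %.3f (S = %d, n = %d), p = %.4g\n",
              x$tau, as.integer(x$s), x$n, x$p_value))
  invisible(x)
}

#' Sen's slope (median of pairwise slopes)
#'
#' @param values numeric series; missing values dropped with their years.
#' @param years time index; pairs with equal years are skipped.
#' @return slope in value units per year unit.
#' @export
sen_slope <- function(values, years = seq_along(values)) {
  ok <- is.finite(values)
  v <- values[ok]; t <- years[ok]
  n <- length(v)
  if (n < 2) stop("need at least 2 non-missing values")
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    dt <- t[(i + 1):n] - t[i]
    slopes <- c(slopes, (v[(i + 1):n] - v[i])[dt != 0] / dt[dt != 0])
  }
  stats::median(slopes)
}

#' Trend in the annual odds of an extreme-heat event
#'
#' Maximum-likelihood logistic regression (via iteratively reweighted least
#' squares) of a yearly event indicator on calendar year. Reports the
#' fitted odds ratio per year, the equivalent percent change per year, and
#' a Wald confidence interval. Complete separation is detected and
#' reported, not silently accepted.
#'
#' @param indicator 0/1 (or logical) event indicator per year; missing
#'   years dropped.
#' @param years calendar years.
#' @param conf confidence level for the Wald interval.
#' @return list with `odds_ratio` (per year), `pct_per_year`, `ci_low`,
#'   `ci_high` (odds-ratio scale), `p_value`, `n`, `separation`.
#' @export
event_odds_trend <- function(indicator, years, conf = 0.95) {
  ok <- is.finite(indicator)
  y <- as.numeric(indicator[ok]); t <- as.numeric(years[ok])
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ t, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || abs(stats::coef(fit)[2]) > 10) sep <- TRUE
  beta <- stats::coef(fit)[["t"]]
  se <- sqrt(stats::vcov(fit)["t", "t"])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  list(odds_ratio = exp(beta),
       pct_per_year = 100 * (exp(beta) - 1),
       ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       p_value = pval, n = length(y), separation = sep)
}

#' Seasonal annual means of a daily series
#'
#' @param series `daily_sst` data frame.
#' @param window `"annual"`, `"summer"` (Jun-Aug) or `"winter"` (Dec-Feb,
#'   with December assigned to the following January's year).
#' @param var column to average (`"sst"` or `"psu"`).
#' @return data frame with `year` and `value` (NA for years with no data in
#'   the window).
#' @export
annual_means <- function(series, window = c("annual", "summer", "winter"),
                         var = "sst") {
  window <- match.arg(window)
  yr <- as.integer(format(series$date, "%Y"))
  mo <- as.integer(format(series$date, "%m"))
  if (window == "summer") {
    keep <- mo %in% 6:8
  } else if (window == "winter") {
    keep <- mo %in% c(12, 1, 2)
    yr[mo == 12] <- yr[mo == 12] + 1L  # December belongs to the next winter
  } else keep <- rep(TRUE, nrow(series))
  yr <- yr[keep]; v <- series[[var]][keep]
  years <- seq(min(yr), max(yr))
  value <- vapply(years, function(y) {
    sel <- yr == y
    if (!any(sel)) NA_real_ else mean(v[sel], na.rm = TRUE)
  }, 0)
  data.frame(year = years, value = value)
}

#' Decadal rate of change from a penalized smoother
#'
#' Fits a cubic smoothing spline (smoothing parameter chosen by generalized
#' cross-validation) to annual means and reports the mean first derivative
#' over the period, scaled to degrees (or PSU) per decade, plus the implied
#' total change over the period and a residual-bootstrap percentile CI.
#'
#' @param annual data frame with `year` and `value` (NAs dropped).
#' @param period length-2 year range over which to average the derivative;
#'   default the full data range.
#' @param n_boot residual-bootstrap resamples.
#' @param seed integer seed (mandatory when `n_boot > 0`).
#' @param conf confidence level.
#' @return list with `rate_per_decade`, `total_change`, `ci_low`, `ci_high`
#'   (per-decade scale), `period`, `n`.
#' @export
trend_rate <- function(annual, period = NULL, n_boot = 500, seed,
                       conf = 0.95) {
  ok <- is.finite(annual$value)
  x <- annual$year[ok]; y <- annual$value[ok]
  if (length(x) < 10) stop("need at least 10 annual values")
  if (is.null(period)) period <- range(x)
  if (period[1] < min(x) || period[2] > max(x))
    stop("period outside data range")
  eval_years <- seq(period[1], period[2])
  rate_of <- function(yy) {
    fit <- stats::smooth.spline(x, yy, cv = FALSE)  # GCV
    mean(stats::predict(fit, eval_years, deriv = 1)$y)
  }
  rate <- rate_of(y)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (missing(seed)) stop("seed is mandatory for the bootstrap CI")
    set.seed(as.integer(seed))
    fit0 <- stats::smooth.spline(x, y, cv = FALSE)
    fitted0 <- stats::predict(fit0, x)$y
    res <- y - fitted0
    boot <- vapply(seq_len(n_boot), function(b)
      rate_of(fitted0 + sample(res, length(res), replace = TRUE)), 0)
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)) * 10)
  }
  list(rate_per_decade = rate * 10,
       total_change = rate * (period[2] - period[1]),
       ci_low = ci[1], ci_high = ci[2],
       period = period, n = length(x))
}

#' Baseline anomalies and Pearson correlation of two annual series
#'
#' Each series is re-expressed as anomalies from its own mean over the
#' baseline period (default 1971-2000), then the Pearson correlation is
#' computed over the overlapping years.
#'
#' @param a,b data frames with `year` and `value`.
#' @param baseline_years length-2 inclusive year range for the baseline.
#' @return list with `anomaly_a`, `anomaly_b` (data frames), `r`,
#'   `p_value`, `n_overlap`.
#' @export
anomalies_and_correlation <- function(a, b, baseline_years = c(1971, 2000)) {
  anomalize <- function(df) {
    base <- df$value[df$year >= baseline_years[1] &
                       df$year <= baseline_years[2] & is.finite(df$value)]
    if (length(base) == 0)
      stop("no baseline years present in series")
    data.frame(year = df$year, value = df$value - mean(base))
  }
  aa <- anomalize(a); bb <- anomalize(b)
  m <- merge(aa, bb, by = "year", suffixes = c("_a", "_b"))
  m <- m[is.finite(m$value_a) & is.finite(m$value_b), ]
  if (nrow(m) < 3) stop("need at least 3 overlapping years")
  ct <- stats::cor.test(m$value_a, m$value_b, method = "pearson")
  list(anomaly_a = aa, anomaly_b = bb,
       r = unname(ct$estimate), p_value = ct$p.value,
       n_overlap = nrow(m))
}
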