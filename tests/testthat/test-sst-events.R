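test_that("days_above counts within the seasonal window and flags gaps", {
  # constant 17.9: threshold 18 never reached
  s <- toy_series("2000-01-01", "2002-12-31", 17.9)
  d <- days_above(s, 18)
  expect_true(all(d$n_days == 0))
  # constant 20 over Jun-Aug: full window length (92 days)
  s2 <- toy_series("2000-01-01", "2000-12-31", 20)
  expect_equal(days_above(s2, 20)$n_days, 92)
  # missing years are NA, not zero
  s3 <- daily_sst_series(c(seq(as.Date("2000-06-01"), as.Date("2000-08-31"), "day"),
                           seq(as.Date("2002-06-01"), as.Date("2002-08-31"), "day")),
                         rep(19, 184))
  d3 <- days_above(s3, 18)
  expect_equal(d3$n_days[d3$year == 2001], NA_integer_)
  expect_equal(d3$n_days[d3$year == 2000], 92)
  # monotone in threshold: days >= 18 always >= days >= 20
  set.seed(41)
  s4 <- daily_sst_series(seq(as.Date("2000-01-01"), as.Date("2005-12-31"), "day"),
                         15 + rnorm(2192, 0, 3))
  d18 <- days_above(s4, 18); d20 <- days_above(s4, 20)
  expect_true(all(d18$n_days >= d20$n_days))
  expect_error(days_above(s4[0, ], 18), "empty")
})

test_that("detect_events finds maximal runs with inclusive thresholds", {
  # 13 days at 18.5 -> no stress event (boundary)
  pad <- function(core, n = 5) c(rep(10, n), core, rep(10, n))
  mk <- function(sst) daily_sst_series(
    seq(as.Date("2001-05-01"), by = "day", length.out = length(sst)), sst)
  expect_equal(nrow(detect_stress_events(mk(pad(rep(18.5, 13))))), 0)
  # 14 days at exactly 18.0 -> one event, length 14 ("at or above")
  ev <- detect_stress_events(mk(pad(rep(18, 14))))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$length, 14L)
  # 20-day run >= 20 -> one mortality event of length 20, not two
  evm <- detect_mortality_events(mk(pad(rep(20.3, 20))))
  expect_equal(nrow(evm), 1)
  expect_equal(evm$length, 20L)
  # 7-day run at 20 -> one mortality event
  expect_equal(nrow(detect_mortality_events(mk(pad(rep(20, 7))))), 1)
  # every reported event day satisfies sst >= threshold
  set.seed(43)
  s <- daily_sst_series(seq(as.Date("2000-01-01"), as.Date("2003-12-31"), "day"),
                        16 + 3 * sin(seq(0, 40, length.out = 1461)) +
                          rnorm(1461, 0, 0.5))
  evs <- detect_events(s, 18, 3)
  for (k in seq_len(nrow(evs))) {
    idx <- s$date >= evs$start_date[k] & s$date <= evs$end_date[k]
    expect_true(all(s$sst[idx] >= 18))
    # maximality: neighbours below threshold or absent
    before <- s$sst[s$date == evs$start_date[k] - 1]
    after <- s$sst[s$date == evs$end_date[k] + 1]
    if (length(before)) expect_lt(before, 18)
    if (length(after)) expect_lt(after, 18)
  }
})

test_that("a data gap breaks a run and never merges events", {
  d1 <- seq(as.Date("2001-07-01"), as.Date("2001-07-10"), "day")
  d2 <- seq(as.Date("2001-07-12"), as.Date("2001-07-21"), "day")  # 1-day hole
  s <- daily_sst_series(c(d1, d2), rep(19, 20))
  ev <- detect_events(s, 18, 7)
  expect_equal(nrow(ev), 2)   # two 10-day runs, not one 21-day event
  expect_true(all(ev$length == 10))
  expect_equal(nrow(detect_events(s, 18, 14)), 0)  # neither run reaches 14
})

test_that("mann_kendall matches exhaustive enumeration and cor.test", {
  # strictly increasing -> tau = 1
  mk <- mann_kendall(1:8)
  expect_equal(mk$tau, 1)
  expect_equal(mk$s, 28)
  # antisymmetry: opposite tau, equal p
  set.seed(47)
  v <- rnorm(9)
  a <- mann_kendall(v); b <- mann_kendall(-v)
  expect_equal(a$tau, -b$tau)
  expect_equal(a$p_value, b$p_value)
  # brute-force oracle at n <= 10, with and without ties
  for (i in 1:10) {
    v <- sample(round(rnorm(8), 1))  # rounding induces occasional ties
    s_brute <- 0
    for (j in 1:7) for (k in (j + 1):8) s_brute <- s_brute + sign(v[k] - v[j])
    mk <- mann_kendall(v)
    expect_equal(mk$s, s_brute)
    expect_equal(mk$tau, unname(cor(seq_along(v), v, method = "kendall")),
                 tolerance = 1e-12)
  }
  # all equal -> tau 0, p 1
  flat <- mann_kendall(rep(2, 6))
  expect_equal(flat$tau, 0); expect_equal(flat$p_value, 1)
  expect_error(mann_kendall(c(1, 2, 3)), "at least 4")
})

test_that("sen_slope is the median of enumerated pairwise slopes", {
  # exact line: slope recovered exactly
  expect_equal(sen_slope(0.36 * (2000:2020), 2000:2020), 0.36)
  expect_equal(sen_slope(c(1, 2, 4), c(0, 1, 2)), 1.5)  # median{1, 1.5, 2}
  expect_equal(sen_slope(rep(3, 5)), 0)
  # enumeration oracle on random series
  set.seed(53)
  for (i in 1:10) {
    v <- rnorm(7); t <- sort(sample(1990:2020, 7))
    slopes <- c()
    for (j in 1:6) for (k in (j + 1):7)
      slopes <- c(slopes, (v[k] - v[j]) / (t[k] - t[j]))
    expect_equal(sen_slope(v, t), median(slopes))
  }
  # tau sign agrees with sen slope sign when nonzero
  for (i in 1:10) {
    v <- cumsum(rnorm(12, 0.2))
    ss <- sen_slope(v)
    if (ss != 0) expect_equal(sign(mann_kendall(v)$tau), sign(ss))
  }
  expect_error(sen_slope(3), "at least 2")
})

test_that("event_odds_trend: null behaviour, separation, input checks", {
  set.seed(59)
  # indicator independent of year -> OR ~ 1
  y <- rbinom(400, 1, 0.5)
  r <- event_odds_trend(y, seq_len(400))
  expect_equal(r$odds_ratio, 1, tolerance = 0.01)
  expect_true(r$ci_low <= 1 && 1 <= r$ci_high)
  expect_equal(r$pct_per_year, 100 * (r$odds_ratio - 1))
  # all-zero (or all-one) outcome refused
  expect_error(event_odds_trend(rep(0, 20), 1:20), "both outcome classes")
  # complete separation detected and reported
  sep <- event_odds_trend(c(rep(0, 10), rep(1, 10)), 1:20)
  expect_true(sep$separation)
})

test_that("trend_rate reproduces exact lines and flat series", {
  yrs <- 1970:2020
  # exact line at 0.033 degC/yr -> 0.33 degC/decade
  lin <- data.frame(year = yrs, value = 10 + 0.033 * (yrs - 1970))
  r <- trend_rate(lin, n_boot = 0)
  expect_equal(r$rate_per_decade, 0.33, tolerance = 1e-6)
  expect_equal(r$total_change, 0.033 * 50, tolerance = 1e-6)
  # constant series -> rate 0
  r0 <- trend_rate(data.frame(year = yrs, value = 9), n_boot = 0)
  expect_equal(r0$rate_per_decade, 0, tolerance = 1e-8)
  expect_error(trend_rate(lin, period = c(1960, 2020), n_boot = 0),
               "outside data range")
  expect_error(trend_rate(lin[1:5, ], n_boot = 0), "at least 10")
  expect_error(trend_rate(lin, n_boot = 100), "seed")
})

test_that("anomalies_and_correlation: self-correlation and hand arithmetic", {
  yrs <- 1960:2010
  set.seed(61)
  a <- data.frame(year = yrs, value = 10 + 0.02 * (yrs - 1960) + rnorm(51, 0, 0.3))
  r <- anomalies_and_correlation(a, a)
  expect_equal(r$r, 1)
  # anomalies of the baseline period average to zero by construction
  base <- r$anomaly_a$value[r$anomaly_a$year %in% 1971:2000]
  expect_equal(mean(base), 0, tolerance = 1e-12)
  # toy 5-year pair matches the direct covariance formula
  a5 <- data.frame(year = 1996:2000, value = c(1, 3, 2, 5, 4))
  b5 <- data.frame(year = 1996:2000, value = c(2, 2, 1, 6, 3))
  r5 <- anomalies_and_correlation(a5, b5, baseline_years = c(1996, 2000))
  direct <- sum((a5$value - mean(a5$value)) * (b5$value - mean(b5$value))) /
    sqrt(sum((a5$value - mean(a5$value))^2) * sum((b5$value - mean(b5$value))^2))
  expect_equal(r5$r, direct)
  expect_error(anomalies_and_correlation(a5, data.frame(year = 1:3, value = 1:3),
                                         baseline_years = c(1996, 2000)),
               "baseline")
})

test_that("annual_means windows: summer, winter year-assignment", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2002-12-31"), "day")
  mo <- as.integer(format(dates, "%m"))
  sst <- ifelse(mo %in% 6:8, 20, ifelse(mo %in% c(12, 1, 2), 5, 12))
  s <- daily_sst_series(dates, sst)
  expect_true(all(annual_means(s, "summer")$value == 20))
  w <- annual_means(s, "winter")
  # December 2000 is assigned to winter 2001
  expect_true(all(w$value[w$year %in% 2001:2002] == 5))
})
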