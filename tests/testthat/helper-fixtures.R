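# Shared in-code fixtures: tiny hand-built worlds used across test files.

# Two-species STI table with a fixed baseline (10 cold, 20 warm, baseline 15).
toy_sti <- function() {
  tab <- data.frame(species = c("cold_sp", "warm_sp"),
                    sti = c(10, 20), affinity = c("cold", "warm"),
                    stringsAsFactors = FALSE)
  attr(tab, "baseline_sti") <- 15
  tab
}

toy_survey <- function(id = "Q1", year = 1972L, depth = 2,
                       cover = c(cold_sp = 0.5, warm_sp = 0.5),
                       substrate = "bedrock") {
  quadrat_survey(id, "T1", year, depth, substrate, cover)
}

toy_pair <- function(id = "Q1", depth = 2,
                     hist_cover = c(cold_sp = 0.5, warm_sp = 0.5),
                     mod_cover = c(cold_sp = 0.2, warm_sp = 0.5),
                     hist_substrate = "bedrock", mod_substrate = "bedrock") {
  paired_quadrat(
    quadrat_survey(id, "T1", 1972L, depth, hist_substrate, hist_cover),
    quadrat_survey(id, "T1", 2023L, depth, mod_substrate, mod_cover))
}

# Constant-temperature daily series over given dates.
toy_series <- function(from, to, sst) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  daily_sst_series(dates, rep_len(sst, length(dates)))
}
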