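test_that("estimate_cti_shift point estimate and degenerate CIs", {
  tab <- toy_sti()
  mk_cti <- function(deltas, depths = seq_along(deltas)) {
    data.frame(quadrat_id = sprintf("Q%d", seq_along(deltas)),
               depth_hist_m = depths,
               cti_historical = 12, cti_modern = 12 + deltas,
               delta_cti = deltas)
  }
  # constant +1 shift -> delta 1, zero-width CI
  sh <- estimate_cti_shift(mk_cti(rep(1, 5)), n_boot = 200, seed = 1)
  expect_equal(sh$delta_cti, 1)
  expect_equal(c(sh$ci_low, sh$ci_high), c(1, 1))
  # identity -> delta 0
  sh0 <- estimate_cti_shift(mk_cti(rep(0, 5)), n_boot = 200, seed = 1)
  expect_equal(sh0$delta_cti, 0)
  # sign of estimate equals sign of mean per-pair difference
  set.seed(5)
  for (i in 1:10) {
    d <- rnorm(8, sample(c(-1, 1), 1) * 0.5)
    sh <- estimate_cti_shift(mk_cti(d), n_boot = 100, seed = i)
    expect_equal(sign(sh$delta_cti), sign(mean(d)))
    expect_lte(sh$ci_low, sh$delta_cti); expect_gte(sh$ci_high, sh$delta_cti)
  }
  expect_error(estimate_cti_shift(mk_cti(c(1, 1)), n_boot = 10, seed = 1),
               "at least 3")
  expect_error(estimate_cti_shift(mk_cti(rep(1, 5)), n_boot = 10), "seed")
})

test_that("spline_model shift method recovers a constant shift", {
  set.seed(21)
  n <- 30
  depths <- runif(n, 0, 8)
  base <- 11 + 0.2 * depths
  cti <- data.frame(quadrat_id = sprintf("Q%d", 1:n), depth_hist_m = depths,
                    cti_historical = base + rnorm(n, 0, 0.1),
                    cti_modern = base + 1.4 + rnorm(n, 0, 0.1))
  cti$delta_cti <- cti$cti_modern - cti$cti_historical
  sh <- estimate_cti_shift(cti, method = "spline_model", seed = 1)
  expect_equal(sh$delta_cti, 1.4, tolerance = 0.1)
  expect_true(sh$ci_low <= sh$delta_cti && sh$delta_cti <= sh$ci_high)
})

test_that("assign_process implements the sign x affinity rule", {
  expect_equal(assign_process(-0.4, "cold"), "deborealization")
  expect_equal(assign_process(+0.2, "warm"), "tropicalization")
  expect_equal(assign_process(+0.1, "cold"), "borealization")
  expect_equal(assign_process(-0.1, "warm"), "detropicalization")
  expect_error(assign_process(0, "cold"), "nonzero")
})

test_that("decompose_cti_change: forced, hand-arithmetic and bin-mean cases", {
  tab <- toy_sti()
  # single cold species declines, nothing else changes -> deborealization 1
  p1 <- list(toy_pair(hist_cover = c(cold_sp = 0.6, warm_sp = 0.2),
                      mod_cover = c(cold_sp = 0.2, warm_sp = 0.2)))
  d1 <- decompose_cti_change(p1, tab)
  expect_equal(unname(d1$proportions["deborealization"]), 1)
  expect_equal(dominant_process(d1), "deborealization")

  # one bin: cold -0.6, warm +0.2 -> debor 0.75, trop 0.25
  p2 <- list(toy_pair(hist_cover = c(cold_sp = 0.8, warm_sp = 0.1),
                      mod_cover = c(cold_sp = 0.2, warm_sp = 0.3)))
  d2 <- decompose_cti_change(p2, tab)
  expect_equal(unname(d2$proportions[c("deborealization", "tropicalization")]),
               c(0.75, 0.25))

  # two bins with proportions (1,0,0,0) and (0.5,0.5,0,0) -> mean (0.75,...)
  p3 <- list(
    toy_pair("Q1", depth = 0.5, hist_cover = c(warm_sp = 0.2),
             mod_cover = c(warm_sp = 0.6)),                     # trop only
    toy_pair("Q2", depth = 1.5, hist_cover = c(warm_sp = 0.2, cold_sp = 0.5),
             mod_cover = c(warm_sp = 0.5, cold_sp = 0.2)))      # 0.5 / 0.5
  d3 <- decompose_cti_change(p3, tab)
  expect_equal(unname(d3$proportions["tropicalization"]), 0.75)
  expect_equal(unname(d3$proportions["deborealization"]), 0.25)
  # l1 bin weighting: bins weighted by share of absolute change (0.4 vs 0.6)
  d3b <- decompose_cti_change(p3, tab, bin_weighting = "l1")
  expect_equal(unname(d3b$proportions["tropicalization"]),
               (0.4 * 1 + 0.6 * 0.5) / 1)

  # no change anywhere -> all-zero flag, dominant_process refuses
  p0 <- list(toy_pair(hist_cover = c(cold_sp = 0.5), mod_cover = c(cold_sp = 0.5)))
  d0 <- decompose_cti_change(p0, tab)
  expect_true(d0$no_change)
  expect_true(all(d0$proportions == 0))
  expect_error(dominant_process(d0), "no dominant")
})

test_that("decomposition properties: sum to one, duplication invariance, single-bin equivalence", {
  set.seed(31)
  tab <- data.frame(species = letters[1:6],
                    sti = c(9, 10, 11, 16, 17, 18),
                    affinity = c("cold", "cold", "cold", "warm", "warm", "warm"))
  rand_pairs <- function(n, depth_max = 4) {
    lapply(seq_len(n), function(i)
      toy_pair(sprintf("Q%d", i), depth = runif(1, 0, depth_max),
               hist_cover = stats::setNames(runif(6), letters[1:6]),
               mod_cover = stats::setNames(runif(6), letters[1:6])))
  }
  for (rep in 1:10) {
    pairs <- rand_pairs(8)
    d <- decompose_cti_change(pairs, tab)
    expect_equal(sum(d$proportions), 1, tolerance = 1e-12)
    expect_true(all(d$proportions >= 0))
    # duplicating every quadrat leaves bin means, hence proportions, unchanged
    d2 <- decompose_cti_change(c(pairs, pairs), tab)
    expect_equal(d2$proportions, d$proportions, tolerance = 1e-12)
  }
  # single-bin dataset equals the unbinned global tally (brute force oracle)
  pairs <- rand_pairs(6, depth_max = 0.9)  # all depths in bin [0, 1)
  d <- decompose_cti_change(pairs, tab)
  hist_mean <- colMeans(do.call(rbind, lapply(pairs, function(p)
    p$historical$cover[letters[1:6]])))
  mod_mean <- colMeans(do.call(rbind, lapply(pairs, function(p)
    p$modern$cover[letters[1:6]])))
  delta <- mod_mean - hist_mean
  w <- abs(delta) / sum(abs(delta))
  aff <- stats::setNames(tab$affinity, tab$species)
  brute <- c(tropicalization = 0, deborealization = 0,
             borealization = 0, detropicalization = 0)
  for (sp in names(delta)) {
    if (delta[[sp]] != 0)
      brute[assign_process(delta[[sp]], aff[[sp]])] <-
        brute[assign_process(delta[[sp]], aff[[sp]])] + w[[sp]]
  }
  expect_equal(d$proportions, brute, tolerance = 1e-12)
})

test_that("dominant_process reports ties as a set", {
  tab <- toy_sti()
  pairs <- list(toy_pair(hist_cover = c(cold_sp = 0.5, warm_sp = 0.2),
                         mod_cover = c(cold_sp = 0.2, warm_sp = 0.5)))
  d <- decompose_cti_change(pairs, tab)
  expect_setequal(dominant_process(d), c("deborealization", "tropicalization"))
})
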