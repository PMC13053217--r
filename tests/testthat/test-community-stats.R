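test_that("bray_curtis: worked values and properties", {
  expect_equal(bray_curtis(c(0.5, 0.2), c(0.5, 0.2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)   # disjoint supports
  # hand arithmetic
  expect_equal(bray_curtis(c(0.88, 0.03), c(0.16, 0.38)),
               (0.72 + 0.35) / (1.04 + 0.41))
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 2), c(1, 1)), "nonnegative")
  set.seed(7)
  for (i in 1:25) {
    x <- runif(5); y <- runif(5)
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))          # symmetric
    expect_gte(d, 0); expect_lte(d, 1)          # bounded
    expect_equal(bray_curtis(x, x), 0)
  }
})

test_that("bray_curtis_matrix matches vegan on random communities", {
  skip_if_not_installed("vegan")
  set.seed(13)
  x <- matrix(rlnorm(10 * 6), 10, 6)
  expect_equal(unname(bray_curtis_matrix(x)),
               unname(as.matrix(vegan::vegdist(x, "bray"))),
               tolerance = 1e-12)
})

test_that("permanova pseudo-F matches vegan's adonis2", {
  skip_if_not_installed("vegan")
  set.seed(17)
  x <- matrix(rlnorm(12 * 7), 12, 7)
  g <- rep(c("a", "b"), each = 6)
  f_ours <- permanova(bray_curtis_matrix(x), g, n_perm = 99, seed = 1)$statistic
  f_vegan <- vegan::adonis2(x ~ g, permutations = 19)$F[1]
  expect_equal(f_ours, f_vegan, tolerance = 1e-10)
  # three groups too
  g3 <- rep(c("a", "b", "c"), each = 4)
  f3 <- permanova(bray_curtis_matrix(x), g3, n_perm = 2000, seed = 1)$statistic
  expect_equal(f3, vegan::adonis2(x ~ g3, permutations = 19)$F[1],
               tolerance = 1e-10)
})

test_that("permanova: separation, enumeration oracle, input checks", {
  set.seed(19)
  # two well-separated clouds -> smallest attainable exhaustive p
  x <- rbind(matrix(runif(4 * 5, 0, 0.1), 4, 5),
             matrix(runif(4 * 5, 5, 5.1), 4, 5))
  g <- rep(1:2, each = 4)
  r <- permanova(bray_curtis_matrix(x), g, n_perm = 999, seed = 1)
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / choose(8, 4))  # obs and its mirror relabeling
  # Monte-Carlo p within 3 binomial SE of exhaustive p on 3+3 samples
  x6 <- matrix(rlnorm(6 * 5), 6, 5)
  g6 <- rep(1:2, each = 3)
  dm6 <- bray_curtis_matrix(x6)
  exact <- permanova(dm6, g6, n_perm = choose(6, 3), seed = 1)
  expect_true(exact$exact)
  mc <- permanova(dm6, g6, n_perm = 999, seed = 42)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 999)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1 / 1000)
  # errors
  expect_error(permanova(dm6, c(1, 1, 1, 1, 1, 2), n_perm = 9, seed = 1),
               "at least 2 samples")
  expect_error(permanova(dm6, rep(1, 6), n_perm = 9, seed = 1),
               "at least 2 groups")
  expect_error(permanova(matrix(0, 4, 4), rep(1:2, 2), n_perm = 9, seed = 1))
})

test_that("permanova paired scheme swaps labels within quadrat blocks", {
  set.seed(23)
  x <- matrix(rlnorm(12 * 5), 12, 5)
  g <- rep(1:2, 6)
  strata <- rep(1:6, each = 2)
  r <- permanova(bray_curtis_matrix(x), g, n_perm = 199, seed = 3,
                 scheme = "paired", strata = strata)
  expect_equal(r$scheme, "paired")
  expect_gte(r$p_value, 1 / 200); expect_lte(r$p_value, 1)
  expect_error(permanova(bray_curtis_matrix(x), g, n_perm = 99, seed = 1,
                         scheme = "paired"), "strata")
})

test_that("dispersion_homogeneity: Euclidean closed form and direction", {
  # on Euclidean distances the PCoA embedding is exact, so distances to the
  # group centroid must match the direct Euclidean computation
  set.seed(29)
  pts <- rbind(matrix(rnorm(10, 0, 1), 5, 2), matrix(rnorm(10, 4, 2), 5, 2))
  g <- rep(1:2, each = 5)
  dm <- as.matrix(stats::dist(pts))
  r <- dispersion_homogeneity(dm, g)
  direct <- unlist(lapply(split(seq_len(10), g), function(idx) {
    cen <- colMeans(pts[idx, , drop = FALSE])
    sqrt(rowSums(sweep(pts[idx, , drop = FALSE], 2, cen)^2))
  }), use.names = FALSE)
  expect_equal(sort(r$distances), sort(direct), tolerance = 1e-9)
  # identical internal geometry (translated cloud) -> F ~ 0, p ~ 1
  cloud <- matrix(rnorm(10), 5, 2)
  pts2 <- rbind(cloud, cloud + 100)
  r2 <- dispersion_homogeneity(as.matrix(stats::dist(pts2)), rep(1:2, each = 5))
  expect_lt(abs(r2$statistic), 1e-6)
  expect_gt(r2$p_value, 0.99)
  # one tight, one diffuse cloud -> large F, small p
  set.seed(31)
  pts3 <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
                matrix(rnorm(20, 0, 5), 10, 2))
  r3 <- dispersion_homogeneity(as.matrix(stats::dist(pts3)), rep(1:2, each = 10))
  expect_lt(r3$p_value, 0.05)
})

test_that("simper contributions: identity, oracle, and vegan agreement", {
  # single differing species -> 100%
  x <- rbind(c(0.5, 0.2), c(0.5, 0.2), c(0.5, 0.8), c(0.5, 0.8))
  colnames(x) <- c("same", "diff")
  s <- simper(x, rep(1:2, each = 2))
  expect_equal(s$percent[s$species == "diff"], 100)
  # per-pair contributions sum to that pair's Bray-Curtis: with one pair per
  # group the total equals the pair dissimilarity
  x2 <- rbind(a = c(0.88, 0.03, 0.1), b = c(0.16, 0.38, 0.1))
  s2 <- simper(x2, c(1, 2))
  expect_equal(attr(s2, "mean_dissimilarity"), bray_curtis(x2[1, ], x2[2, ]))
  # 2x2 toy community against an exhaustive hand tally
  xa <- c(1, 0); xb <- c(0.5, 0.5); xc <- c(0, 1); xd <- c(0.2, 0.8)
  x3 <- rbind(xa, xb, xc, xd)
  g3 <- c(1, 1, 2, 2)
  tally <- matrix(0, 2, 2)  # species x pair
  pairs <- list(list(xa, xc), list(xa, xd), list(xb, xc), list(xb, xd))
  contrib <- sapply(pairs, function(p) abs(p[[1]] - p[[2]]) / sum(p[[1]] + p[[2]]))
  s3 <- simper(x3, g3)
  expect_equal(s3$contribution[order(s3$species)],
               rowMeans(contrib)[order(c("sp1", "sp2"))], tolerance = 1e-12)
  # vegan oracle
  skip_if_not_installed("vegan")
  set.seed(37)
  x4 <- matrix(rlnorm(8 * 5), 8, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  g4 <- rep(c("h", "m"), each = 4)
  sv <- summary(vegan::simper(x4, g4))[[1]]
  so <- simper(x4, g4)
  expect_equal(so$contribution[match(rownames(sv), so$species)],
               sv$average, tolerance = 1e-10)
  expect_error(simper(x4, rep("h", 8)), "two groups")
})
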