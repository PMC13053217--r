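# First-principles dissimilarity and permutation statistics for community
# restructuring: Bray-Curtis, one-way PERMANOVA, homogeneity of multivariate
# dispersion, and SIMPER. vegan is used only as an independent oracle in the
# test suite, never here.

#' Bray-Curtis dissimilarity between two cover vectors
#'
#' `d = sum(|x - y|) / sum(x + y)`, computed on untransformed cover so that
#' changes in dominant species carry the most weight. Bounded in \[0, 1\];
#' 0 iff the vectors are equal, 1 for disjoint supports.
#'
#' @param x,y equal-length nonnegative numeric vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("cover vectors must be nonnegative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero samples")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix of a community matrix
#'
#' @param x samples-by-species nonnegative matrix; every row must have a
#'   positive total.
#' @return symmetric `dist`-free base matrix of pairwise dissimilarities
#'   with the row names of `x`.
#' @export
bray_curtis_matrix <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("cover matrix must be nonnegative")
  rs <- rowSums(x)
  if (any(rs == 0)) stop("all-zero sample row(s): ",
                         paste(which(rs == 0), collapse = ", "))
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(xi - x[j, ])) / (rs[i] + rs[j])
    }
  }
  d
}

.check_dm <- function(dm) {
  dm <- as.matrix(dm)
  stopifnot(nrow(dm) == ncol(dm))
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal not zero")
  dm
}

# One-way pseudo-F from a squared-distance matrix and integer group codes.
# SS_total = sum_{i<j} d2 / N ; SS_within = sum_g (1/n_g) sum_{i<j in g} d2.
.pseudo_F <- function(d2, g, a, N) {
  ssw <- 0
  for (lev in seq_len(a)) {
    idx <- which(g == lev)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  sst <- sum(d2) / (2 * N)
  ssb <- sst - ssw
  (ssb / (a - 1)) / (ssw / (N - a))
}

#' Permutational multivariate analysis of variance (one-way PERMANOVA)
#'
#' Partitions squared dissimilarities into between- and within-group
#' components and tests the pseudo-F statistic by free permutation of the
#' group labels. When the number of distinct label arrangements for two
#' groups is at most `n_perm`, the exact permutation distribution is
#' enumerated instead of sampled and the p-value is the exact tail
#' proportion; otherwise the Monte-Carlo p-value uses the add-one
#' correction `p = (#{perm F >= obs F} + 1) / (n_perm + 1)`.
#'
#' A paired design can be honoured with `scheme = "paired"`, which swaps
#' the two labels within each block of `strata` independently instead of
#' permuting freely.
#'
#' @param dm symmetric dissimilarity matrix.
#' @param groups group labels, one per sample; at least 2 groups with at
#'   least 2 samples each.
#' @param n_perm number of permutations.
#' @param seed integer seed (mandatory for Monte-Carlo sampling).
#' @param scheme `"free"` (default) or `"paired"`.
#' @param strata block factor (e.g. quadrat id), required for
#'   `scheme = "paired"`.
#' @return object of class `perm_test`: list with `statistic`, `p_value`,
#'   `n_perm` (NA under exhaustive enumeration), `exact`, `seed`, `scheme`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed, scheme = c("free", "paired"),
                      strata = NULL) {
  scheme <- match.arg(scheme)
  dm <- .check_dm(dm)
  g <- as.integer(factor(groups))
  N <- length(g)
  stopifnot(N == nrow(dm))
  a <- max(g)
  if (a < 2) stop("need at least 2 groups")
  if (any(tabulate(g, a) < 2)) stop("every group needs at least 2 samples")
  d2 <- dm^2
  obs <- .pseudo_F(d2, g, a, N)
  if (!is.finite(obs)) stop("pseudo-F undefined (zero within-group variation)")

  if (scheme == "paired") {
    if (missing(seed)) stop("seed is mandatory")
    if (is.null(strata)) stop("scheme = 'paired' requires strata")
    if (a != 2) stop("paired scheme requires exactly 2 groups")
    blocks <- split(seq_len(N), strata)
    if (any(lengths(blocks) != 2))
      stop("paired scheme requires exactly 2 samples per stratum")
    set.seed(as.integer(seed))
    stat <- vapply(seq_len(n_perm), function(k) {
      gp <- g
      flip <- as.logical(stats::rbinom(length(blocks), 1, 0.5))
      for (b in which(flip)) gp[blocks[[b]]] <- rev(gp[blocks[[b]]])
      .pseudo_F(d2, gp, a, N)
    }, 0)
    p <- (sum(stat >= obs) + 1) / (n_perm + 1)
    return(structure(list(statistic = obs, p_value = p, n_perm = n_perm,
                          exact = FALSE, seed = as.integer(seed),
                          scheme = scheme), class = "perm_test"))
  }

  n1 <- sum(g == 1)
  exhaustive <- a == 2 && choose(N, n1) <= n_perm
  if (exhaustive) {
    combs <- utils::combn(N, n1)
    stat <- apply(combs, 2, function(idx) {
      gp <- rep(2L, N); gp[idx] <- 1L
      .pseudo_F(d2, gp, a, N)
    })
    p <- mean(stat >= obs - 1e-12)
    structure(list(statistic = obs, p_value = p, n_perm = NA_integer_,
                   exact = TRUE, seed = NA_integer_, scheme = scheme),
              class = "perm_test")
  } else {
    if (missing(seed)) stop("seed is mandatory")
    set.seed(as.integer(seed))
    stat <- vapply(seq_len(n_perm),
                   function(k) .pseudo_F(d2, g[sample.int(N)], a, N), 0)
    p <- (sum(stat >= obs) + 1) / (n_perm + 1)
    structure(list(statistic = obs, p_value = p, n_perm = n_perm,
                   exact = FALSE, seed = as.integer(seed), scheme = scheme),
              class = "perm_test")
  }
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: statistic = %.4f, p = %.4g (%s)\n",
              x$statistic, x$p_value,
              if (isTRUE(x$exact)) "exhaustive"
              else paste0(x$n_perm, " permutations")))
  invisible(x)
}

#' Principal-coordinate embedding of a dissimilarity matrix
#'
#' Eigendecomposition of the doubly-centred matrix `-d^2 / 2`; axes with
#' eigenvalues at or below a tolerance (including all negative axes of a
#' non-Euclidean input) are dropped without correction.
#'
#' @param dm symmetric dissimilarity matrix.
#' @param tol eigenvalue tolerance relative to the largest eigenvalue.
#' @return list with `points` (samples x axes) and `eig` (all eigenvalues).
#' @export
pcoa_embed <- function(dm, tol = 1e-9) {
  dm <- .check_dm(dm)
  n <- nrow(dm)
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (all(e$values <= tol * max(abs(e$values))))
    stop("principal-coordinate embedding failed: no positive eigenvalues")
  keep <- e$values > tol * max(abs(e$values))
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(pts) <- rownames(dm)
  list(points = pts, eig = e$values)
}

#' Homogeneity of multivariate dispersion between groups
#'
#' Embeds the samples by principal coordinates (negative axes dropped),
#' measures each sample's Euclidean distance to its group centroid in that
#' space, and applies a classical one-way ANOVA F-test to those distances.
#' This is the assumption check that accompanies PERMANOVA: a significant
#' result means group differences may reflect unequal spread rather than
#' location.
#'
#' @inheritParams permanova
#' @return object of class `perm_test` with the ANOVA F and its classical
#'   p-value (`n_perm = NA`), plus `distances` (per-sample distance to
#'   group centroid).
#' @export
dispersion_homogeneity <- function(dm, groups) {
  dm <- .check_dm(dm)
  g <- factor(groups)
  stopifnot(length(g) == nrow(dm))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  pts <- pcoa_embed(dm)$points
  dist_to_centroid <- numeric(nrow(pts))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    centroid <- colMeans(pts[idx, , drop = FALSE])
    dist_to_centroid[idx] <-
      sqrt(rowSums(sweep(pts[idx, , drop = FALSE], 2, centroid)^2))
  }
  fit <- stats::oneway.test(dist_to_centroid ~ g, var.equal = TRUE)
  structure(list(statistic = unname(fit$statistic),
                 p_value = unname(fit$p.value),
                 n_perm = NA_integer_, exact = FALSE, seed = NA_integer_,
                 scheme = "anova", distances = dist_to_centroid),
            class = "perm_test")
}

#' SIMPER: per-species contributions to between-group dissimilarity
#'
#' For every between-group sample pair, species `k` contributes
#' `|x_ik - x_jk| / sum_m(x_im + x_jm)` to that pair's Bray-Curtis
#' dissimilarity; the species' overall contribution is the mean over all
#' between-group pairs, so the contributions sum exactly to the mean
#' between-group dissimilarity.
#'
#' @param x samples-by-species nonnegative cover matrix.
#' @param groups two-level grouping vector.
#' @return data frame (ranked by contribution) with `species`,
#'   `contribution` (absolute, sums to the mean between-group
#'   dissimilarity), `percent`, `mean_a`, `mean_b` (group mean covers);
#'   attribute `mean_dissimilarity`.
#' @export
simper <- function(x, groups) {
  x <- as.matrix(x)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("SIMPER requires exactly two groups")
  ia <- which(g == levels(g)[1]); ib <- which(g == levels(g)[2])
  if (length(ia) == 0 || length(ib) == 0) stop("empty group")
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  contrib <- numeric(ncol(x))
  n_pairs <- 0L
  for (i in ia) for (j in ib) {
    denom <- sum(x[i, ] + x[j, ])
    if (denom == 0) stop("pair of all-zero samples")
    contrib <- contrib + abs(x[i, ] - x[j, ]) / denom
    n_pairs <- n_pairs + 1L
  }
  contrib <- contrib / n_pairs
  out <- data.frame(species = colnames(x),
                    contribution = unname(contrib),
                    percent = 100 * unname(contrib) / sum(contrib),
                    mean_a = unname(colMeans(x[ia, , drop = FALSE])),
                    mean_b = unname(colMeans(x[ib, , drop = FALSE])),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution), ]
  rownames(out) <- NULL
  attr(out, "mean_dissimilarity") <- sum(contrib)
  out
}
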