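# CTI shift between timepoints and its decomposition into the four thermal
# processes (tropicalization, detropicalization, borealization,
# deborealization) with a 1-m depth-bin correction for the shallow bias of
# the historical sampling.

.processes <- c("tropicalization", "deborealization",
                "borealization", "detropicalization")

#' Estimate the community temperature index shift between timepoints
#'
#' Default `paired_bootstrap` method: the point estimate is the mean over
#' quadrat pairs of (modern CTI - historical CTI); the confidence interval
#' is a percentile bootstrap over quadrats. The alternative `spline_model`
#' method mirrors the depth-structured estimate: a Gaussian GAM of CTI with
#' a year effect, a year-stratified depth smoother and a per-quadrat random
#' intercept, with the shift taken as the difference of marginal means
#' integrated over the observed depth range.
#'
#' @param cti per-pair CTI table from [cti_table()] (rows with NA CTIs are
#'   dropped).
#' @param method `"paired_bootstrap"` (default) or `"spline_model"`.
#' @param n_boot bootstrap resamples for the percentile CI.
#' @param seed integer seed (mandatory; every stochastic step is seeded).
#' @param conf confidence level.
#' @return object of class `cti_shift`: list with `delta_cti`, `ci_low`,
#'   `ci_high`, `method`, `n_pairs`, `conf`.
#' @export
estimate_cti_shift <- function(cti, method = c("paired_bootstrap", "spline_model"),
                               n_boot = 2000, seed, conf = 0.95) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is mandatory")
  cc <- cti[stats::complete.cases(cti[, c("cti_historical", "cti_modern")]), ]
  n <- nrow(cc)
  if (n < 3) stop("need at least 3 pairs with CTI at both timepoints")
  d <- cc$cti_modern - cc$cti_historical
  if (method == "paired_bootstrap") {
    delta <- mean(d)
    set.seed(as.integer(seed))
    boot <- vapply(seq_len(n_boot),
                   function(i) mean(d[sample.int(n, n, replace = TRUE)]), 0)
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  } else {
    long <- data.frame(
      cti = c(cc$cti_historical, cc$cti_modern),
      depth = rep(cc$depth_hist_m, 2),
      year = factor(rep(c("historical", "modern"), each = n)),
      quadrat = factor(rep(cc$quadrat_id, 2)))
    k <- max(3, min(10, floor(n / 2)))
    fit <- mgcv::gam(cti ~ year + s(depth, by = year, k = k) +
                       s(quadrat, bs = "re"),
                     data = long, method = "REML")
    grid_depth <- seq(min(long$depth), max(long$depth), length.out = 101)
    newd <- expand.grid(depth = grid_depth,
                        year = levels(long$year),
                        quadrat = long$quadrat[1])
    pr <- stats::predict(fit, newdata = newd, type = "response",
                         exclude = "s(quadrat)", newdata.guaranteed = TRUE)
    mm <- tapply(pr, newd$year, mean)
    delta <- unname(mm["modern"] - mm["historical"])
    # delta-method CI on the difference of depth-integrated marginal means
    Xp <- stats::predict(fit, newdata = newd, type = "lpmatrix",
                         exclude = "s(quadrat)", newdata.guaranteed = TRUE)
    w <- ifelse(newd$year == "modern", 1, -1) / length(grid_depth)
    cvec <- colSums(Xp * w)
    se <- sqrt(drop(t(cvec) %*% fit$Vp %*% cvec))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- c(delta - z * se, delta + z * se)
  }
  structure(list(delta_cti = delta, ci_low = ci[1], ci_high = ci[2],
                 method = method, n_pairs = n, conf = conf),
            class = "cti_shift")
}

#' @export
print.cti_shift <- function(x, ...) {
  cat(sprintf("CTI shift: %+.3f degC (%d%% CI: %.3f to %.3f; %s, n = %d pairs)\n",
              x$delta_cti, round(100 * x$conf), x$ci_low, x$ci_high,
              x$method, x$n_pairs))
  invisible(x)
}

#' Assign a thermal process to one species' cover change
#'
#' A warm-affinity species gaining cover contributes to tropicalization and
#' losing cover to detropicalization; a cold-affinity species gaining cover
#' contributes to borealization and losing cover to deborealization. A zero
#' change carries no process.
#'
#' @param delta_cover signed change in cover fraction (modern - historical),
#'   nonzero.
#' @param affinity `"warm"` or `"cold"`.
#' @return one of `"tropicalization"`, `"detropicalization"`,
#'   `"borealization"`, `"deborealization"`.
#' @export
assign_process <- function(delta_cover, affinity) {
  affinity <- match.arg(affinity, c("warm", "cold"))
  if (!is.finite(delta_cover) || delta_cover == 0)
    stop("delta_cover must be nonzero (zero change carries no process)")
  if (affinity == "warm") {
    if (delta_cover > 0) "tropicalization" else "detropicalization"
  } else {
    if (delta_cover > 0) "borealization" else "deborealization"
  }
}

#' Decompose the CTI change into the four thermal processes
#'
#' Quadrats are grouped into depth bins (half-open `[k, k+1)` m on the
#' historical depth, 1 m wide by default) to counteract the shallow bias of
#' the historical sampling. Within each bin, per-species cover is averaged
#' across quadrats at each timepoint and the change `delta = modern -
#' historical` computed; each changed species gets weight
#' `|delta| / sum(|delta|)` within the bin and its weight accrues to the
#' process given by [assign_process()]. Overall proportions are the
#' unweighted mean of the bin proportions over bins with any change
#' (`bin_weighting = "equal"`, default) or the mean weighted by each bin's
#' share of total absolute cover change (`"l1"`).
#'
#' @param pairs list of `paired_quadrat` objects.
#' @param sti_table classified STI table from [classify_affinity()].
#' @param bin_width depth bin width in meters.
#' @param bin_weighting `"equal"` or `"l1"`.
#' @param species optional restriction to a species subset (default: the
#'   species in `sti_table`, i.e. the same rare-species filter as the CTI).
#' @return object of class `process_decomposition`: list with `proportions`
#'   (named numeric over the four processes), `per_species` (data frame of
#'   depth-averaged weights and process per species), `bins` (per-bin
#'   detail), `no_change` flag.
#' @export
decompose_cti_change <- function(pairs, sti_table, bin_width = 1,
                                 bin_weighting = c("equal", "l1"),
                                 species = NULL) {
  bin_weighting <- match.arg(bin_weighting)
  stopifnot(length(pairs) >= 1, bin_width > 0)
  if (any(is.na(sti_table$affinity)))
    stop("affinities not assigned; run classify_affinity() first")
  if (is.null(species)) species <- sti_table$species
  affinity <- stats::setNames(sti_table$affinity, sti_table$species)

  depth <- vapply(pairs, function(p) p$historical$depth_m, 0)
  bin_id <- floor(depth / bin_width)

  cover_of <- function(s, sp) if (sp %in% names(s$cover)) s$cover[[sp]] else 0
  bin_rows <- list(); per_species_w <- list()
  for (b in sort(unique(bin_id))) {
    in_bin <- pairs[bin_id == b]
    dmean <- vapply(species, function(sp) {
      mean(vapply(in_bin, function(p) cover_of(p$modern, sp), 0)) -
        mean(vapply(in_bin, function(p) cover_of(p$historical, sp), 0))
    }, 0)
    changed <- dmean != 0
    tot <- sum(abs(dmean[changed]))
    props <- stats::setNames(numeric(4), .processes)
    if (tot > 0) {
      w <- abs(dmean[changed]) / tot
      proc <- mapply(assign_process, dmean[changed],
                     affinity[names(dmean)[changed]])
      for (p in .processes) props[p] <- sum(w[proc == p])
      per_species_w[[as.character(b)]] <-
        data.frame(bin = b, species = names(dmean)[changed],
                   delta_cover = unname(dmean[changed]),
                   weight = unname(w), process = unname(proc),
                   stringsAsFactors = FALSE)
    }
    bin_rows[[as.character(b)]] <-
      data.frame(bin = b, depth_lo = b * bin_width,
                 depth_hi = (b + 1) * bin_width,
                 n_pairs = length(in_bin), total_abs_change = tot,
                 t(props), stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, bin_rows); rownames(bins) <- NULL
  active <- bins$total_abs_change > 0
  if (!any(active)) {
    proportions <- stats::setNames(numeric(4), .processes)
    no_change <- TRUE
    per_species <- data.frame(species = character(0), mean_weight = numeric(0),
                              process = character(0), stringsAsFactors = FALSE)
  } else {
    no_change <- FALSE
    bw <- if (bin_weighting == "equal") {
      as.numeric(active) / sum(active)
    } else {
      bins$total_abs_change / sum(bins$total_abs_change)
    }
    proportions <- vapply(.processes,
                          function(p) sum(bw * bins[[p]]), 0)
    psw <- do.call(rbind, per_species_w)
    agg <- stats::aggregate(weight ~ species + process, data = psw,
                            FUN = function(z) sum(z) / sum(active))
    names(agg)[names(agg) == "weight"] <- "mean_weight"
    per_species <- agg[order(-agg$mean_weight), c("species", "mean_weight", "process")]
    rownames(per_species) <- NULL
  }
  structure(list(proportions = proportions, per_species = per_species,
                 bins = bins, no_change = no_change,
                 bin_width = bin_width, bin_weighting = bin_weighting),
            class = "process_decomposition")
}

#' @export
print.process_decomposition <- function(x, ...) {
  if (x$no_change) {
    cat("process decomposition: no cover change anywhere (all proportions 0)\n")
  } else {
    cat("process decomposition (", x$bin_weighting, "-weighted ",
        x$bin_width, "-m depth bins):\n", sep = "")
    for (p in names(x$proportions))
      cat(sprintf("  %-18s %6.1f%%\n", p, 100 * x$proportions[[p]]))
  }
  invisible(x)
}

#' Dominant thermal process of a decomposition
#'
#' @param decomp a `process_decomposition`.
#' @return character vector of the process(es) with the maximum proportion
#'   (length > 1 on exact ties).
#' @export
dominant_process <- function(decomp) {
  stopifnot(inherits(decomp, "process_decomposition"))
  if (decomp$no_change) stop("no cover change anywhere: no dominant process")
  p <- decomp$proportions
  names(p)[p == max(p)]
}
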