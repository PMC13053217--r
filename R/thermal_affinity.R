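# Species temperature indices from a latitude-binned coastal SST
# climatology, warm/cold affinity classification against the historical
# community mean, and abundance-weighted community temperature indices.

#' Bin coastal SST samples latitudinally
#'
#' Collapses coastal (latitude, SST) samples into a fixed-width latitudinal
#' climatology so that stretches of coastline running east-west do not get
#' extra weight. Bin centers sit at multiples of `bin_width` and each bin is
#' half-open, `[center - w/2, center + w/2)`; empty bins are omitted. The
#' default 0.1 degree width matches the resolution at which species range
#' limits are recorded.
#'
#' @param samples data frame (or list) with numeric `lat` and `sst`.
#' @param bin_width bin width in degrees latitude.
#' @return object of class `climatology`: data frame with `lat_center` and
#'   `mean_sst`, sorted by latitude, plus a `bin_width` attribute.
#' @export
bin_climatology <- function(samples, bin_width = 0.1) {
  lat <- as.numeric(samples$lat); sst <- as.numeric(samples$sst)
  if (length(lat) == 0) stop("need at least one (lat, sst) sample")
  if (any(!is.finite(lat)) || any(!is.finite(sst)))
    stop("non-finite latitude or SST sample")
  stopifnot(bin_width > 0)
  # half-open bins [c - w/2, c + w/2): a sample on the boundary joins the
  # upper bin; round() would send exact halves to even centers instead.
  idx <- floor(round(lat / bin_width + 0.5, 9))
  means <- tapply(sst, idx, mean)
  centers <- as.numeric(names(means)) * bin_width
  ord <- order(centers)
  out <- data.frame(lat_center = centers[ord],
                    mean_sst = as.numeric(means)[ord])
  attr(out, "bin_width") <- bin_width
  class(out) <- c("climatology", "data.frame")
  out
}

#' Climatology from a pre-binned table
#'
#' @param df data frame with `lat_center` and `mean_sst`.
#' @param bin_width bin width in degrees latitude.
#' @return `climatology` object.
#' @export
as_climatology <- function(df, bin_width = 0.1) {
  stopifnot(all(c("lat_center", "mean_sst") %in% names(df)))
  out <- df[order(df$lat_center), c("lat_center", "mean_sst")]
  rownames(out) <- NULL
  if (any(!is.finite(out$mean_sst))) stop("non-finite SST in climatology")
  if (anyDuplicated(out$lat_center)) stop("duplicate bin centers")
  attr(out, "bin_width") <- bin_width
  class(out) <- c("climatology", "data.frame")
  out
}

#' Species temperature index (STI)
#'
#' The STI is the average temperature experienced across a species'
#' latitudinal range: the unweighted mean of climatology bin values whose
#' centers fall inside `[lat_min, lat_max]`.
#'
#' @param species a `species_record` (or any list with `lat_min`,
#'   `lat_max`, `name`).
#' @param clim a `climatology`.
#' @return STI in degrees Celsius.
#' @export
compute_sti <- function(species, clim) {
  stopifnot(inherits(clim, "climatology"))
  inside <- clim$lat_center >= species$lat_min &
    clim$lat_center <= species$lat_max
  if (!any(inside))
    stop("no climatology bins overlap the range of ",
         if (!is.null(species$name)) species$name else "species")
  mean(clim$mean_sst[inside])
}

#' Build species thermal records (STI for every species)
#'
#' @param records list of `species_record` objects (named or not).
#' @param clim a `climatology`.
#' @return data frame with `species`, `sti` and an `affinity` column of NAs
#'   awaiting [classify_affinity()].
#' @export
compute_sti_table <- function(records, clim) {
  sti <- vapply(records, compute_sti, 0, clim = clim)
  data.frame(species = vapply(records, `[[`, "", "name"),
             sti = unname(sti),
             affinity = NA_character_,
             stringsAsFactors = FALSE)
}

#' Classify species as warm- or cold-affinity
#'
#' The baseline is the unweighted mean STI over the species documented in
#' the historical surveys. Every species (from either timepoint) with STI
#' strictly above that baseline is `warm`; all others, including exact
#' ties, are `cold` (warm affinity requires an STI *higher than* the
#' historical community mean).
#'
#' @param sti_table data frame from [compute_sti_table()].
#' @param historical_species character vector of species documented at the
#'   historical timepoint; must be a non-empty subset of
#'   `sti_table$species`.
#' @return `sti_table` with `affinity` filled in and the baseline attached
#'   as attribute `baseline_sti`.
#' @export
classify_affinity <- function(sti_table, historical_species) {
  historical_species <- canonical_species_name(historical_species)
  if (length(historical_species) == 0)
    stop("historical species set is empty")
  missing <- setdiff(historical_species, sti_table$species)
  if (length(missing) > 0)
    stop("historical species lack STI values: ",
         paste(missing, collapse = ", "))
  baseline <- mean(sti_table$sti[sti_table$species %in% historical_species])
  sti_table$affinity <- ifelse(sti_table$sti > baseline, "warm", "cold")
  attr(sti_table, "baseline_sti") <- baseline
  sti_table
}

#' Community temperature index (CTI) of one quadrat survey
#'
#' The CTI is the cover-weighted mean STI of the species present:
#' `sum(cover * STI) / sum(cover)` over species that carry an STI (i.e.
#' passed the rare-species filter). It is invariant to uniform rescaling of
#' cover and always lies between the minimum and maximum STI of the species
#' present.
#'
#' @param survey a `quadrat_survey`.
#' @param sti_table data frame with `species` and `sti` columns.
#' @return CTI in degrees Celsius.
#' @export
compute_cti <- function(survey, sti_table) {
  sti <- stats::setNames(sti_table$sti, sti_table$species)
  common <- intersect(names(survey$cover), names(sti))
  w <- survey$cover[common]
  keep <- w > 0
  if (sum(w[keep]) <= 0)
    stop("empty community: no positive cover among species with an STI in quadrat ",
         survey$quadrat_id)
  sum(w[keep] * sti[common][keep]) / sum(w[keep])
}

#' Per-quadrat CTI table for a set of paired quadrats
#'
#' @param pairs list of `paired_quadrat` objects.
#' @param sti_table data frame with `species` and `sti`.
#' @return data frame with one row per pair: `quadrat_id`, `depth_hist_m`,
#'   `cti_historical`, `cti_modern`, `delta_cti`. Quadrats where either
#'   timepoint has no scored species get NA CTIs.
#' @export
cti_table <- function(pairs, sti_table) {
  one <- function(s) tryCatch(compute_cti(s, sti_table),
                              error = function(e) NA_real_)
  h <- vapply(pairs, function(p) one(p$historical), 0)
  m <- vapply(pairs, function(p) one(p$modern), 0)
  data.frame(quadrat_id = vapply(pairs, `[[`, "", "quadrat_id"),
             depth_hist_m = vapply(pairs, function(p) p$historical$depth_m, 0),
             cti_historical = h, cti_modern = m, delta_cti = m - h,
             stringsAsFactors = FALSE)
}
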