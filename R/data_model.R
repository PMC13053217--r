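# Domain types and survey-table plumbing shared by every stage:
# cover-code conversion, quadrat filtering/pairing rules, CSV readers/writers.

#' Braun-Blanquet cover code midpoints
#'
#' The modified Braun-Blanquet scale used in the quadrat surveys maps ordinal
#' cover classes to percent-cover bins: `5` = 76-100%, `4` = 51-75%,
#' `3` = 26-50%, `2` = 6-25%, `1` = 1-5%, `+` = <1%. Each code is converted
#' to the midpoint of its bin, expressed as a fraction, e.g. `"5"` becomes
#' 0.88. The `+` bin is open below 1% and has no printed midpoint; its value
#' defaults to 0.005 (midpoint of (0, 0.01)) and can be overridden.
#'
#' @param code character vector of cover codes; each must be one of
#'   `"+"`, `"1"`, ..., `"5"`.
#' @param plus_value fraction assigned to the `"+"` (<1%) class.
#' @return numeric vector of cover fractions in (0, 1].
#' @examples
#' cover_code_to_fraction(c("5", "3", "+"))
#' @export
cover_code_to_fraction <- function(code, plus_value = 0.005) {
  stopifnot(is.numeric(plus_value), length(plus_value) == 1,
            plus_value > 0, plus_value < 0.01)
  map <- c("+" = plus_value,
           "1" = (0.01 + 0.05) / 2,   # 0.03
           "2" = (0.06 + 0.25) / 2,   # 0.155
           "3" = (0.26 + 0.50) / 2,   # 0.38
           "4" = (0.51 + 0.75) / 2,   # 0.63
           "5" = (0.76 + 1.00) / 2)   # 0.88
  code <- as.character(code)
  bad <- setdiff(unique(code), names(map))
  if (length(bad) > 0) {
    stop("unknown cover code(s): ", paste(sQuote(bad), collapse = ", "))
  }
  unname(map[code])
}

.substrate_levels <- c("sand", "pebble", "cobble", "boulder", "bedrock")

#' Construct a quadrat survey
#'
#' One quadrat observed at one timepoint. Cover values are fractions in
#' \[0, 1\] per species; the total may exceed 1 because canopy and understory
#' layers overlap. Depths are meters below chart datum (positive downward);
#' intertidal (negative) depths are rejected because the survey design is
#' strictly subtidal.
#'
#' @param quadrat_id,transect_id character identifiers.
#' @param year integer timepoint label.
#' @param depth_m depth in meters below chart datum, finite and >= 0.
#' @param substrate character vector, subset of
#'   `c("sand", "pebble", "cobble", "boulder", "bedrock")`.
#' @param cover named numeric vector, species name -> cover fraction in
#'   \[0, 1\].
#' @return an object of class `quadrat_survey`.
#' @export
quadrat_survey <- function(quadrat_id, transect_id, year, depth_m,
                           substrate, cover) {
  stopifnot(is.character(quadrat_id), length(quadrat_id) == 1,
            length(year) == 1, length(depth_m) == 1)
  year <- as.integer(year)
  depth_m <- as.numeric(depth_m)
  if (!is.finite(depth_m)) stop("depth_m must be finite")
  if (depth_m < 0) stop("negative depth_m (intertidal) not supported")
  substrate <- unique(as.character(substrate))
  bad <- setdiff(substrate, .substrate_levels)
  if (length(bad) > 0) stop("unknown substrate(s): ", paste(bad, collapse = ", "))
  cover <- unlist(cover)
  if (length(cover) > 0) {
    if (is.null(names(cover)) || any(!nzchar(names(cover))))
      stop("cover must be a named vector (species -> fraction)")
    if (anyDuplicated(names(cover)))
      stop("duplicate species in cover vector")
    if (any(!is.finite(cover)) || any(cover < 0) || any(cover > 1))
      stop("cover fractions must lie in [0, 1]")
  }
  structure(list(quadrat_id = quadrat_id,
                 transect_id = as.character(transect_id),
                 year = year, depth_m = depth_m,
                 substrate = substrate, cover = cover),
            class = "quadrat_survey")
}

#' @export
print.quadrat_survey <- function(x, ...) {
  cat(sprintf("quadrat %s (transect %s), year %d, %.1f m, %d species\n",
              x$quadrat_id, x$transect_id, x$year, x$depth_m,
              length(x$cover)))
  invisible(x)
}

#' Pair a historical and a modern survey of the same quadrat
#'
#' @param historical,modern `quadrat_survey` objects sharing `quadrat_id`
#'   but with different years.
#' @return an object of class `paired_quadrat`.
#' @export
paired_quadrat <- function(historical, modern) {
  stopifnot(inherits(historical, "quadrat_survey"),
            inherits(modern, "quadrat_survey"))
  if (historical$quadrat_id != modern$quadrat_id)
    stop("paired surveys must share quadrat_id")
  if (historical$year == modern$year)
    stop("paired surveys must have different years")
  if (historical$year > modern$year) { tmp <- historical; historical <- modern; modern <- tmp }
  structure(list(quadrat_id = historical$quadrat_id,
                 historical = historical, modern = modern),
            class = "paired_quadrat")
}

#' Drop quadrat pairs whose substrate was sand-only at either timepoint
#'
#' Sand-only quadrats (bare sand or eelgrass over mobile sand) are excluded
#' from community-change analyses because their cover dynamics reflect
#' sediment movement rather than macroalgal change. A pair is excluded when
#' the substrate recorded at the historical and/or the modern timepoint is
#' exactly `"sand"`.
#'
#' @param pairs list of `paired_quadrat` objects.
#' @return list with elements `retained` (list of pairs) and `excluded`
#'   (data frame of `quadrat_id`, `reason`). Counts always satisfy
#'   `length(retained) + nrow(excluded) == length(pairs)`.
#' @export
filter_quadrats <- function(pairs) {
  stopifnot(is.list(pairs))
  sand_only <- function(s) identical(sort(s$substrate), "sand")
  keep <- logical(length(pairs))
  reasons <- character(0); ids <- character(0)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    stopifnot(inherits(p, "paired_quadrat"))
    h <- sand_only(p$historical); m <- sand_only(p$modern)
    if (h || m) {
      ids <- c(ids, p$quadrat_id)
      reasons <- c(reasons,
                   if (h && m) "sand-only at both timepoints"
                   else if (h) "sand-only at historical timepoint"
                   else "sand-only at modern timepoint")
    } else keep[i] <- TRUE
  }
  list(retained = pairs[keep],
       excluded = data.frame(quadrat_id = ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Identify non-rare species across a set of paired quadrats
#'
#' A species is retained when its cover reaches `threshold` (default 5%) in
#' at least one quadrat at either timepoint. The retained set is
#' monotonically decreasing in `threshold`.
#'
#' @param pairs list of `paired_quadrat` objects.
#' @param threshold minimum cover fraction, in \[0, 1).
#' @return character vector of retained species names.
#' @export
rare_species_filter <- function(pairs, threshold = 0.05) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold < 1)
  max_cover <- numeric(0)
  for (p in pairs) {
    for (s in list(p$historical, p$modern)) {
      cv <- s$cover
      for (sp in names(cv)) {
        max_cover[sp] <- max(max_cover[sp], cv[[sp]], na.rm = TRUE)
      }
    }
  }
  sort(names(max_cover)[max_cover >= threshold & max_cover > 0])
}

#' Construct a species metadata record
#'
#' @param name species name (matched elsewhere after trimming and
#'   case-folding; synonym resolution is the caller's job).
#' @param functional_group one of `kelp`, `red_blade`, `green_blade`,
#'   `thick_turf`, `thin_turf`, `articulated_coralline`, `introduced`.
#' @param lat_min,lat_max latitudinal range limits in decimal degrees,
#'   `lat_min < lat_max`.
#' @return object of class `species_record`.
#' @export
species_record <- function(name, functional_group, lat_min, lat_max) {
  groups <- c("kelp", "red_blade", "green_blade", "thick_turf",
              "thin_turf", "articulated_coralline", "introduced")
  functional_group <- match.arg(functional_group, groups)
  lat_min <- as.numeric(lat_min); lat_max <- as.numeric(lat_max)
  if (!is.finite(lat_min) || !is.finite(lat_max) || lat_min >= lat_max)
    stop("require finite lat_min < lat_max")
  structure(list(name = canonical_species_name(name),
                 functional_group = functional_group,
                 lat_min = lat_min, lat_max = lat_max),
            class = "species_record")
}

#' Canonicalize a species name for matching
#'
#' Trims surrounding whitespace and case-folds. No taxonomic synonym
#' resolution is attempted.
#' @param x character vector of names.
#' @return canonical names.
#' @export
canonical_species_name <- function(x) {
  tolower(trimws(as.character(x)))
}

.required_survey_cols <- c("quadrat_id", "transect_id", "year", "depth_m",
                           "substrate", "species")

#' Read quadrat surveys from a long-format CSV
#'
#' Expected columns: `quadrat_id`, `transect_id`, `year`, `depth_m`,
#' `substrate` (semicolon-separated categories), `species`, and exactly one
#' of `cover_code` (Braun-Blanquet symbol) or `cover_fraction`. Rows with
#' the same (`quadrat_id`, `year`) describe one survey; a quadrat with no
#' species is encoded with an empty `species` field.
#'
#' @param path CSV file path.
#' @param plus_value passed to [cover_code_to_fraction()] when the file uses
#'   cover codes.
#' @return list of `quadrat_survey` objects, ordered by (`quadrat_id`,
#'   `year`).
#' @export
read_surveys <- function(path, plus_value = 0.005) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(quadrat_id = "character",
                                       transect_id = "character"))
  missing <- setdiff(.required_survey_cols, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  has_code <- "cover_code" %in% names(df)
  has_frac <- "cover_fraction" %in% names(df)
  if (has_code && has_frac)
    stop("table must have cover_code or cover_fraction, not both")
  if (!has_code && !has_frac)
    stop("table must have a cover_code or cover_fraction column")
  occupied <- !is.na(df$species) & nzchar(df$species)
  if (has_code) {
    df$cover_fraction <- NA_real_
    df$cover_fraction[occupied] <-
      cover_code_to_fraction(df$cover_code[occupied], plus_value)
  } else {
    cv <- df$cover_fraction[occupied]
    if (any(!is.finite(cv)) || any(cv < 0) || any(cv > 1))
      stop("cover_fraction outside [0, 1]")
  }
  df$species[occupied] <- canonical_species_name(df$species[occupied])
  key <- paste(df$quadrat_id, df$year, df$species, sep = "\r")
  if (anyDuplicated(key[occupied]))
    stop("duplicate (quadrat_id, year, species) rows")
  surveys <- list()
  for (grp in split(df, paste(df$quadrat_id, df$year, sep = "\r"))) {
    occ <- !is.na(grp$species) & nzchar(grp$species)
    cover <- stats::setNames(grp$cover_fraction[occ], grp$species[occ])
    surveys[[length(surveys) + 1L]] <- quadrat_survey(
      quadrat_id = grp$quadrat_id[1], transect_id = grp$transect_id[1],
      year = grp$year[1], depth_m = grp$depth_m[1],
      substrate = strsplit(grp$substrate[1], ";", fixed = TRUE)[[1]],
      cover = cover)
  }
  ord <- order(vapply(surveys, `[[`, "", "quadrat_id"),
               vapply(surveys, `[[`, 0L, "year"))
  surveys[ord]
}

#' Write quadrat surveys to the canonical long-format CSV
#'
#' The canonical form uses a `cover_fraction` column, species sorted within
#' each survey, and surveys ordered by (`quadrat_id`, `year`), so that
#' `write_surveys()` then [read_surveys()] round-trips byte-identically.
#'
#' @param surveys list of `quadrat_survey` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(surveys, path) {
  ord <- order(vapply(surveys, `[[`, "", "quadrat_id"),
               vapply(surveys, `[[`, 0L, "year"))
  rows <- lapply(surveys[ord], function(s) {
    sp <- sort(names(s$cover))
    n <- max(length(sp), 1L)
    data.frame(quadrat_id = rep(s$quadrat_id, n),
               transect_id = rep(s$transect_id, n),
               year = rep(s$year, n),
               depth_m = rep(s$depth_m, n),
               substrate = rep(paste(s$substrate, collapse = ";"), n),
               species = if (length(sp)) sp else "",
               cover_fraction = if (length(sp)) unname(s$cover[sp]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read species metadata (name, functional group, latitudinal limits)
#'
#' @param path CSV with columns `name`, `functional_group`, `lat_min`,
#'   `lat_max`.
#' @return list of `species_record` objects named by canonical species name.
#' @export
read_species_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "functional_group", "lat_min", "lat_max")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  recs <- lapply(seq_len(nrow(df)), function(i)
    species_record(df$name[i], df$functional_group[i],
                   df$lat_min[i], df$lat_max[i]))
  stats::setNames(recs, vapply(recs, `[[`, "", "name"))
}

#' Build paired quadrats from a flat list of surveys
#'
#' Surveys sharing a `quadrat_id` across exactly two distinct years are
#' paired (earlier year = historical). Quadrats present at only one
#' timepoint are dropped with a log entry.
#'
#' @param surveys list of `quadrat_survey` objects.
#' @return list with `pairs` (list of `paired_quadrat`) and `unpaired`
#'   (character vector of quadrat ids lacking a partner).
#' @export
pair_surveys <- function(surveys) {
  ids <- vapply(surveys, `[[`, "", "quadrat_id")
  pairs <- list(); unpaired <- character(0)
  for (id in unique(ids)) {
    ss <- surveys[ids == id]
    yrs <- vapply(ss, `[[`, 0L, "year")
    if (length(ss) == 2 && yrs[1] != yrs[2]) {
      o <- order(yrs)
      pairs[[length(pairs) + 1L]] <- paired_quadrat(ss[[o[1]]], ss[[o[2]]])
    } else {
      unpaired <- c(unpaired, id)
    }
  }
  list(pairs = pairs, unpaired = unpaired)
}

#' Community matrix (samples x species) from paired quadrats
#'
#' Builds the wide cover matrix used by the dissimilarity statistics, one
#' row per quadrat-timepoint, with a grouping vector of years.
#'
#' @param pairs list of `paired_quadrat` objects.
#' @param species optional character vector restricting (and ordering) the
#'   columns, e.g. the output of [rare_species_filter()]; default: all
#'   species observed.
#' @return list with `x` (numeric matrix, rownames `quadrat_id@year`),
#'   `groups` (integer years), `quadrat` (character ids).
#' @export
community_matrix <- function(pairs, species = NULL) {
  surveys <- unlist(lapply(pairs, function(p) list(p$historical, p$modern)),
                    recursive = FALSE)
  if (is.null(species)) {
    species <- sort(unique(unlist(lapply(surveys, function(s) names(s$cover)))))
  }
  x <- matrix(0, nrow = length(surveys), ncol = length(species),
              dimnames = list(NULL, species))
  for (i in seq_along(surveys)) {
    cv <- surveys[[i]]$cover
    common <- intersect(names(cv), species)
    x[i, common] <- cv[common]
  }
  rownames(x) <- vapply(surveys, function(s)
    paste0(s$quadrat_id, "@", s$year), "")
  list(x = x,
       groups = vapply(surveys, `[[`, 0L, "year"),
       quadrat = vapply(surveys, `[[`, "", "quadrat_id"))
}
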