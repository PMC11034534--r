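# Areal-interpolation core: block-centroid coverage within urbanicity-specific
# great-circle radii, aggregated to tract-level access results.

#' Mean Earth radius, in miles, of the sphere all distances are computed on
#' @export
earth_radius_miles <- 3958.8

#' Great-circle distance in miles
#'
#' Haversine distance on a sphere of radius 3958.8 miles. Vectorised and
#' recycled over the longer pair of inputs; symmetric, non-negative, and zero
#' exactly for identical points. A spherical model (rather than an ellipsoidal
#' geodesic) keeps the error well below 0.3%, which is negligible against the
#' 0.5-10 mile policy radii.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees WGS84.
#' @return Distance(s) in miles.
#' @examples
#' great_circle_miles(0, 0, 1, 0)   # one degree of latitude, ~69.09 miles
#' @export
great_circle_miles <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) {
    all(is.finite(lat)) && all(is.finite(lon)) &&
      all(lat >= -90 & lat <= 90) && all(lon >= -180 & lon <= 180)
  }
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) {
    stop("invalid coordinate: latitude must lie in [-90, 90], longitude in [-180, 180]",
         call. = FALSE)
  }
  # geosphere uses (lon, lat) axis order; the package API is (lat, lon)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = earth_radius_miles)
}

#' Build a spatial index over pharmacy locations
#'
#' A latitude-sorted index supporting within-radius coverage queries with a
#' conservative latitude/longitude bounding-box prefilter followed by exact
#' haversine tests, so query results are identical to a brute-force scan over
#' all pharmacies.
#'
#' @param pharmacies Pharmacy table with `lat`, `lon` columns (may be empty).
#' @return A `pharmacy_index` object.
#' @export
build_pharmacy_index <- function(pharmacies) {
  ord <- order(pharmacies$lat)
  structure(list(lat = pharmacies$lat[ord], lon = pharmacies$lon[ord],
                 n = nrow(pharmacies)),
            class = "pharmacy_index")
}

#' @export
print.pharmacy_index <- function(x, ...) {
  cat("<pharmacy_index> of", x$n, "pharmacies\n")
  invisible(x)
}

#' Query whether points fall strictly inside any pharmacy's radius
#'
#' @param index A [build_pharmacy_index()] object.
#' @param lat,lon Query coordinates (vectorised).
#' @param radius Radius in miles (> 0).
#' @return Logical vector: `TRUE` where the nearest pharmacy is strictly
#'   closer than `radius`. An empty index returns all `FALSE`.
#' @export
index_covered <- function(index, lat, lon, radius) {
  stopifnot(inherits(index, "pharmacy_index"), radius > 0)
  n <- length(lat)
  if (index$n == 0L) return(rep(FALSE, n))
  # conservative box: 1 deg latitude is the largest degree step anywhere,
  # so pad by 1% over the exact conversion; longitude pad uses the smallest
  # |lat| in the band (largest cos), again conservative
  dlat <- 1.01 * radius / (earth_radius_miles * pi / 180)
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- findInterval(lat[i] - dlat, index$lat) + 1L
    hi <- findInterval(lat[i] + dlat, index$lat)
    if (lo > hi) next
    cand_lat <- index$lat[lo:hi]
    cand_lon <- index$lon[lo:hi]
    min_abs_lat <- max(0, abs(lat[i]) - dlat)
    if (min_abs_lat < 89) {
      dlon <- 1.01 * radius /
        (earth_radius_miles * pi / 180 * cos(min_abs_lat * pi / 180))
      dd <- abs(cand_lon - lon[i])
      keep <- pmin(dd, 360 - dd) <= dlon
      cand_lat <- cand_lat[keep]
      cand_lon <- cand_lon[keep]
    }
    if (length(cand_lat) == 0L) next
    d <- great_circle_miles(lat[i], lon[i], cand_lat, cand_lon)
    out[i] <- any(d < radius)   # strict: at-radius is NOT covered
  }
  out
}

#' Is a block centroid inside any pharmacy's radius?
#'
#' Coverage is strict: a centroid at exactly the radius distance counts as
#' outside, matching the convention that a population living one mile *or
#' more* from a pharmacy is far from it.
#'
#' @param block One-row block table (or list with `lat`, `lon`).
#' @param pharmacies Pharmacy table; an empty table means vacuously uncovered.
#' @param radius Radius in miles (> 0).
#' @return Single logical.
#' @export
block_covered <- function(block, pharmacies, radius) {
  stopifnot(radius > 0)
  if (nrow(pharmacies) == 0L) return(FALSE)
  d <- great_circle_miles(block$lat, block$lon, pharmacies$lat, pharmacies$lon)
  min(d) < radius
}

#' Population-weighted tract centers from block centroids
#'
#' @param blocks Block table.
#' @return Tibble `tract_id`, `lat`, `lon`; the unweighted centroid mean is
#'   used for tracts whose blocks hold zero population.
#' @export
tract_centers <- function(blocks) {
  blocks %>%
    group_by(tract_id) %>%
    summarise(
      lat = if (sum(population) > 0) sum(lat * population) / sum(population)
            else mean(lat),
      lon = if (sum(population) > 0) sum(lon * population) / sum(population)
            else mean(lon),
      .groups = "drop")
}

#' Tract-level access result by block-centroid areal interpolation
#'
#' Sums the population of the tract's blocks whose centroids are strictly
#' inside any pharmacy's radius — considering *all* pharmacies in the dataset,
#' since a block may be served from a neighbouring tract — and flags the tract
#' low-access when the uncovered fraction exceeds the policy's access
#' fraction. Blocks with zero population contribute to neither numerator nor
#' denominator.
#'
#' @param tract One-row tract table.
#' @param blocks_of_tract Blocks belonging to the tract.
#' @param pharmacies Full pharmacy table (or a [build_pharmacy_index()]).
#' @param radius Access radius in miles for this tract.
#' @param policy A [threshold_policy()].
#' @param n_pharmacies_in_tract Optional known pharmacy count for the tract
#'   (filled by [classify_tracts()]); `NA` when unknown here.
#' @return One-row tibble: `tract_id`, `radius_used`, `population_total`,
#'   `population_outside`, `prop_outside`, `low_access`,
#'   `n_pharmacies_in_tract`. A zero-population tract returns the sentinel
#'   `prop_outside = NA`, `low_access = NA`, consumed by the classifier's
#'   zero-population branch.
#' @export
tract_access <- function(tract, blocks_of_tract, pharmacies, radius, policy,
                         n_pharmacies_in_tract = NA_integer_) {
  stopifnot(radius > 0)
  if (!all(blocks_of_tract$tract_id == tract$tract_id)) {
    stop("blocks_of_tract contains blocks of another tract", call. = FALSE)
  }
  index <- if (inherits(pharmacies, "pharmacy_index")) pharmacies
           else build_pharmacy_index(pharmacies)
  pop <- blocks_of_tract$population
  total <- sum(pop)
  if (total == 0L) {
    return(tibble(tract_id = tract$tract_id, radius_used = radius,
                  population_total = 0L, population_outside = 0L,
                  prop_outside = NA_real_, low_access = NA,
                  n_pharmacies_in_tract = as.integer(n_pharmacies_in_tract)))
  }
  live <- pop > 0
  covered <- index_covered(index, blocks_of_tract$lat[live],
                           blocks_of_tract$lon[live], radius)
  outside <- sum(pop[live][!covered])
  prop <- outside / total
  low <- if (policy$access_strict) prop > policy$access_fraction
         else prop >= policy$access_fraction
  tibble(tract_id = tract$tract_id, radius_used = radius,
         population_total = as.integer(total),
         population_outside = as.integer(outside),
         prop_outside = prop, low_access = low,
         n_pharmacies_in_tract = as.integer(n_pharmacies_in_tract))
}

#' Assign each pharmacy to a tract
#'
#' Uses the pharmacy's own `tract_id` column where present; otherwise the
#' tract of the nearest block centroid (ties broken by smallest `block_id`).
#' Pharmacies that cannot be placed (no blocks) get `NA` and are reported in
#' an explicit "unassigned" bucket downstream.
#'
#' @param pharmacies Pharmacy table.
#' @param blocks Block table.
#' @return Character vector of tract ids aligned with `pharmacies` rows.
#' @export
assign_pharmacy_tracts <- function(pharmacies, blocks) {
  if (nrow(pharmacies) == 0L) return(character(0))
  out <- if ("tract_id" %in% names(pharmacies)) pharmacies$tract_id
         else rep(NA_character_, nrow(pharmacies))
  todo <- which(is.na(out))
  if (length(todo) && nrow(blocks) > 0) {
    ord <- order(blocks$block_id)
    blat <- blocks$lat[ord]; blon <- blocks$lon[ord]
    btr <- blocks$tract_id[ord]
    for (i in todo) {
      d <- great_circle_miles(pharmacies$lat[i], pharmacies$lon[i], blat, blon)
      out[i] <- btr[which.min(d)]   # which.min takes the first = smallest id
    }
  }
  out
}
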