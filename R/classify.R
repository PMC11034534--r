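# Five-way tract verdict: combine urbanicity, the low-income indicator and the
# block-interpolated low-access indicator.

#' Urbanicity class from population density
#'
#' Density is `population / land_area` in persons per square mile. Urban means
#' density at or above `density_urban_min` (the boundary value is urban),
#' rural means strictly below `density_rural_max`, suburban is everything in
#' between.
#'
#' @param tract Tract table (one or more rows) with `population`, `land_area`.
#' @param policy A [threshold_policy()].
#' @return Character vector over [urbanicity_levels].
#' @export
classify_urbanicity <- function(tract, policy) {
  if (any(!is.finite(tract$land_area) | tract$land_area <= 0)) {
    stop("land_area must be > 0 for every tract", call. = FALSE)
  }
  density <- tract$population / tract$land_area
  ifelse(density >= policy$density_urban_min, "urban",
         ifelse(density < policy$density_rural_max, "rural", "suburban"))
}

#' Access radius for a tract
#'
#' The urbanicity class radius (1 / 5 / 10 miles), unless the tract has fewer
#' than `low_vehicle_count` car-owning individuals, in which case the
#' low-vehicle radius applies. By default the override *replaces* the class
#' radius; `low_vehicle_mode = "min"` takes the smaller of the two. A missing
#' car-owner count never triggers the override.
#'
#' @param tract Tract table (vectorised).
#' @param urbanicity Character vector aligned with `tract` rows.
#' @param policy A [threshold_policy()].
#' @return Radii in miles.
#' @export
radius_for <- function(tract, urbanicity, policy) {
  base <- c(urban = policy$radius_urban, suburban = policy$radius_suburban,
            rural = policy$radius_rural)[urbanicity]
  base <- unname(base)
  low_veh <- !is.na(tract$car_owner_count) &
    tract$car_owner_count < policy$low_vehicle_count
  if (policy$low_vehicle_mode == "replace") {
    ifelse(low_veh, policy$radius_low_vehicle, base)
  } else {
    ifelse(low_veh, pmin(policy$radius_low_vehicle, base), base)
  }
}

#' Nearest metropolitan area to a tract
#'
#' Distance is measured from the tract's population-weighted block-centroid
#' mean (unweighted mean when the tract population is zero) to each metro
#' centroid; exact ties go to the lexicographically smaller `metro_id`.
#'
#' @param tract One-row tract table.
#' @param blocks_of_tract The tract's blocks.
#' @param metros Metro table (non-empty).
#' @return The nearest metro as a one-row tibble.
#' @export
nearest_metro <- function(tract, blocks_of_tract, metros) {
  if (nrow(metros) == 0L) stop("no metropolitan areas supplied", call. = FALSE)
  ctr <- tract_centers(blocks_of_tract)
  if (nrow(ctr) != 1L || ctr$tract_id != tract$tract_id) {
    stop("blocks_of_tract must be the blocks of the given tract",
         call. = FALSE)
  }
  m <- metros[order(metros$metro_id), ]
  d <- great_circle_miles(ctr$lat, ctr$lon, m$lat, m$lon)
  m[which.min(d), ]
}

#' Low-income indicator for a tract
#'
#' A tract is low income when 20% or more of its population lives below the
#' Federal Poverty Level (inclusive threshold) *or* its median household
#' income is strictly below 80% of the median income of the nearest
#' metropolitan area. When exactly one of the two income fields is missing the
#' remaining criterion is evaluated alone (an OR with one unknown arm is
#' `TRUE` if the known arm is `TRUE`); when both are missing the result is
#' unknown (`NA`).
#'
#' @param tract One-row tract table.
#' @param metros Metro table (non-empty).
#' @param policy A [threshold_policy()].
#' @param blocks_of_tract The tract's blocks (locates the nearest metro).
#' @return `TRUE`, `FALSE`, or `NA` (unknown).
#' @export
is_low_income <- function(tract, metros, policy, blocks_of_tract) {
  if (nrow(metros) == 0L) stop("no metropolitan areas supplied", call. = FALSE)
  fpl <- tract$prop_below_fpl
  inc <- tract$median_income
  if (is.na(fpl) && is.na(inc)) return(NA)
  fpl_arm <- if (is.na(fpl)) NA else fpl >= policy$fpl_threshold
  rel_arm <- NA
  if (!is.na(inc)) {
    metro <- nearest_metro(tract, blocks_of_tract, metros)
    rel_arm <- inc < policy$metro_income_ratio * metro$median_income
  }
  isTRUE(fpl_arm) || isTRUE(rel_arm)
}

#' Classify every tract
#'
#' Runs the full verdict logic over a dataset: urbanicity from density, the
#' access radius (with the low-vehicle override), block-centroid coverage
#' against all pharmacies, the low-income indicator against the nearest
#' metro, and the five-way verdict. Verdict precedence for degenerate tracts:
#' zero population is `unclassified_zero_pop` regardless of income; missing
#' income (both fields) with population > 0 is `unclassified_no_income`
#' regardless of access.
#'
#' @param blocks,tracts,pharmacies,metros Validated entity tables.
#' @param policy A [threshold_policy()].
#' @param income_gate `TRUE` (default) applies the full desert definition.
#'   `FALSE` runs the access-only sensitivity analysis: income is not
#'   consulted, tracts exceeding the access fraction get verdict
#'   `low_access_only` and no tract gets `desert`; the unclassified
#'   categories are unchanged so both runs classify the same universe.
#' @return Tibble with one row per tract: `tract_id`, `state`, `urbanicity`
#'   (`NA` for zero population), `radius_used`, `population`,
#'   `population_outside`, `prop_outside`, `low_income`, `income_partial`
#'   (exactly one income field was missing), `low_access`,
#'   `n_pharmacies_in_tract`, and `verdict` (factor over [verdict_levels]).
#' @export
classify_tracts <- function(blocks, tracts, pharmacies, metros, policy,
                            income_gate = TRUE) {
  if (nrow(metros) == 0L) stop("no metropolitan areas supplied", call. = FALSE)
  n <- nrow(tracts)
  index <- build_pharmacy_index(pharmacies)

  urb <- classify_urbanicity(tracts, policy)
  urb[tracts$population == 0L] <- NA_character_
  radius <- radius_for(tracts, ifelse(is.na(urb), "rural", urb), policy)

  ph_tract <- assign_pharmacy_tracts(pharmacies, blocks)
  ph_counts <- table(factor(ph_tract, levels = tracts$tract_id))

  centers <- tract_centers(blocks)
  m <- metros[order(metros$metro_id), ]

  blocks_by_tract <- split(blocks, blocks$tract_id)

  res <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- tracts[i, ]
    bl <- blocks_by_tract[[tr$tract_id]]
    if (is.null(bl)) {
      bl <- blocks[0, ]
      if (tr$population > 0L) {
        warning("tract ", tr$tract_id, " has population > 0 but no blocks ",
                "on file; its population is treated as uncovered",
                call. = FALSE)
      }
    }
    pop_total <- tr$population
    if (pop_total == 0L) {
      prop_outside <- NA_real_; pop_outside <- 0L; low_access <- NA
    } else if (nrow(bl) == 0L) {
      prop_outside <- 1; pop_outside <- as.integer(pop_total)
      low_access <- TRUE
    } else {
      acc <- tract_access(tr, bl, index, radius[i], policy)
      prop_outside <- acc$prop_outside
      pop_outside <- acc$population_outside
      low_access <- acc$low_access
    }

    fpl <- tr$prop_below_fpl; inc <- tr$median_income
    income_partial <- xor(is.na(fpl), is.na(inc))
    low_income <- NA
    if (!(is.na(fpl) && is.na(inc))) {
      fpl_arm <- if (is.na(fpl)) NA else fpl >= policy$fpl_threshold
      rel_arm <- NA
      if (!is.na(inc)) {
        ctr <- centers[centers$tract_id == tr$tract_id, ]
        if (nrow(ctr) == 1L) {
          d <- great_circle_miles(ctr$lat, ctr$lon, m$lat, m$lon)
          rel_arm <- inc < policy$metro_income_ratio *
            m$median_income[which.min(d)]
        }
      }
      low_income <- isTRUE(fpl_arm) || isTRUE(rel_arm)
      if (is.na(fpl_arm) && is.na(rel_arm)) low_income <- NA
    }

    verdict <- if (pop_total == 0L) {
      "unclassified_zero_pop"
    } else if (is.na(low_income) && income_gate) {
      "unclassified_no_income"
    } else if (is.na(fpl) && is.na(inc)) {
      "unclassified_no_income"     # same universe in both gate modes
    } else if (income_gate) {
      if (isTRUE(low_access) && isTRUE(low_income)) "desert"
      else if (isTRUE(low_access)) "low_access_only"
      else "not_desert"
    } else {
      if (isTRUE(low_access)) "low_access_only" else "not_desert"
    }

    res[[i]] <- tibble(
      tract_id = tr$tract_id, state = tr$state, urbanicity = urb[i],
      radius_used = radius[i], population = as.integer(pop_total),
      population_outside = as.integer(pop_outside),
      prop_outside = prop_outside, low_income = low_income,
      income_partial = income_partial, low_access = low_access,
      n_pharmacies_in_tract = as.integer(ph_counts[[tr$tract_id]]),
      verdict = verdict)
  }
  out <- bind_rows(res)
  out$verdict <- factor(out$verdict, levels = verdict_levels)
  out
}
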