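#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n across all_of any_of distinct rename row_number pull
#'   group_modify
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Closed vocabularies used across the package ---------------------------------

#' @export
ownership_levels <- c("independent", "chain", "franchise", "government")

#' @export
urbanicity_levels <- c("urban", "suburban", "rural")

#' Five-way tract verdict vocabulary
#'
#' `desert` (low income and low access), `low_access_only`, `not_desert`,
#' `unclassified_no_income` (population > 0 but both income fields missing),
#' `unclassified_zero_pop` (zero population).
#' @export
verdict_levels <- c("desert", "low_access_only", "not_desert",
                    "unclassified_no_income", "unclassified_zero_pop")

#' Service-flag columns on a pharmacy table
#'
#' Logical columns; `NA` means the flag is unknown for that pharmacy, and
#' unknowns are excluded from that flag's group contrast.
#' @export
service_flags <- c("immunization", "ada_accessible", "multidose_packaging",
                   "emergency_24h", "walk_in_clinic", "compounding", "dme")

#' Tract demographic proportion columns recognised by the comparison table
#' @export
demographic_cols <- c("prop_hs_or_less", "prop_uninsured",
                      "prop_public_insurance", "prop_limited_english",
                      "prop_ambulatory_disability", "prop_age_65_plus",
                      "prop_nh_white", "prop_nh_black", "prop_nh_asian",
                      "prop_nh_aian", "prop_hispanic")

# Per-type record validation ---------------------------------------------------
# Each checker returns a tibble of problems (id, problem); an empty tibble
# means every record satisfies the type invariants.

check_coords <- function(lat, lon) {
  bad_lat <- !is.finite(lat) | lat < -90 | lat > 90
  bad_lon <- !is.finite(lon) | lon < -180 | lon > 180
  list(bad = bad_lat | bad_lon,
       why = ifelse(bad_lat, "latitude outside [-90, 90]",
                    "longitude outside [-180, 180]"))
}

problems_tbl <- function(id, bad, why) {
  tibble(id = as.character(id[bad]), problem = why[bad])
}

check_blocks <- function(x) {
  out <- list()
  dup <- duplicated(x$block_id)
  out$dup <- problems_tbl(x$block_id, dup, rep("duplicate block_id", nrow(x)))
  cc <- check_coords(x$lat, x$lon)
  out$coord <- problems_tbl(x$block_id, cc$bad, cc$why)
  bad_pop <- !is.finite(x$population) | x$population < 0 |
    x$population != floor(x$population)
  out$pop <- problems_tbl(x$block_id, bad_pop,
                          rep("population must be a non-negative integer", nrow(x)))
  bind_rows(out)
}

check_tracts <- function(x) {
  out <- list()
  out$dup <- problems_tbl(x$tract_id, duplicated(x$tract_id),
                          rep("duplicate tract_id", nrow(x)))
  bad_area <- !is.finite(x$land_area) | x$land_area <= 0
  out$area <- problems_tbl(x$tract_id, bad_area,
                           rep("land_area must be > 0", nrow(x)))
  bad_pop <- !is.finite(x$population) | x$population < 0
  out$pop <- problems_tbl(x$tract_id, bad_pop,
                          rep("population must be >= 0", nrow(x)))
  bad_inc <- !is.na(x$median_income) & x$median_income < 0
  out$inc <- problems_tbl(x$tract_id, bad_inc,
                          rep("median_income must be >= 0 or missing", nrow(x)))
  bad_fpl <- !is.na(x$prop_below_fpl) &
    (x$prop_below_fpl < 0 | x$prop_below_fpl > 1)
  out$fpl <- problems_tbl(x$tract_id, bad_fpl,
                          rep("prop_below_fpl must lie in [0, 1] or be missing", nrow(x)))
  bad_car <- !is.na(x$car_owner_count) & x$car_owner_count < 0
  out$car <- problems_tbl(x$tract_id, bad_car,
                          rep("car_owner_count must be >= 0 or missing", nrow(x)))
  for (d in intersect(demographic_cols, names(x))) {
    v <- x[[d]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    out[[d]] <- problems_tbl(x$tract_id, bad,
                             rep(paste0(d, " must lie in [0, 1]"), nrow(x)))
  }
  bind_rows(out)
}

check_pharmacies <- function(x) {
  out <- list()
  out$dup <- problems_tbl(x$pharmacy_id, duplicated(x$pharmacy_id),
                          rep("duplicate pharmacy_id", nrow(x)))
  cc <- check_coords(x$lat, x$lon)
  out$coord <- problems_tbl(x$pharmacy_id, cc$bad, cc$why)
  bad_own <- is.na(x$ownership) | !(x$ownership %in% ownership_levels)
  out$own <- problems_tbl(x$pharmacy_id, bad_own,
                          paste0("unknown ownership value: ",
                                 as.character(x$ownership)))
  bind_rows(out)
}

check_metros <- function(x) {
  out <- list()
  out$dup <- problems_tbl(x$metro_id, duplicated(x$metro_id),
                          rep("duplicate metro_id", nrow(x)))
  cc <- check_coords(x$lat, x$lon)
  out$coord <- problems_tbl(x$metro_id, cc$bad, cc$why)
  bad_inc <- !is.finite(x$median_income) | x$median_income <= 0
  out$inc <- problems_tbl(x$metro_id, bad_inc,
                          rep("median_income must be > 0", nrow(x)))
  bind_rows(out)
}

#' Check that tract populations equal the sum of their blocks
#'
#' Areal interpolation assumes tract population is exactly the sum of member
#' block populations; tracts listed here violate that, and tracts with
#' population > 0 but no blocks on file are flagged too (the procedure cannot
#' place their population).
#'
#' @param tracts,blocks Validated tract and block tables.
#' @return Tibble with `tract_id`, `tract_population`, `block_population_sum`
#'   for every inconsistent tract (zero rows when consistent).
#' @export
check_population_consistency <- function(tracts, blocks) {
  sums <- blocks %>%
    group_by(tract_id) %>%
    summarise(block_population_sum = sum(population), .groups = "drop")
  tracts %>%
    select(tract_id, tract_population = population) %>%
    left_join(sums, by = "tract_id") %>%
    mutate(block_population_sum = ifelse(is.na(block_population_sum), 0L,
                                         block_population_sum)) %>%
    filter(tract_population != block_population_sum)
}

required_cols <- list(
  blocks = c("block_id", "tract_id", "lat", "lon", "population"),
  tracts = c("tract_id", "state", "land_area", "population",
             "median_income", "prop_below_fpl", "car_owner_count"),
  pharmacies = c("pharmacy_id", "lat", "lon", "ownership"),
  metros = c("metro_id", "lat", "lon", "median_income")
)
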