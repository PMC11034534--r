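# Synthetic regions with ground-truth verdicts known by construction.
#
# Tracts sit on a sparse grid (30-mile spacing) so pharmacy radii never
# interact across tracts; block offsets are controlled in miles and converted
# to degree offsets with the local metric at the tract's latitude (kept below
# 60 degrees to bound distortion). Every planted quantity carries a margin:
# block centroids sit at <= 0.90 r or >= 1.05 r of the effective radius, and
# income values sit at least 0.02 (poverty share) or 2% (relative income)
# away from their thresholds, so verdicts are stable under coordinate
# round-tripping through files.

miles_per_deg_lat <- function() earth_radius_miles * pi / 180

offset_point <- function(lat, lon, dist_miles, bearing_rad) {
  mpd <- miles_per_deg_lat()
  list(lat = lat + dist_miles * cos(bearing_rad) / mpd,
       lon = lon + dist_miles * sin(bearing_rad) / (mpd * cos(lat * pi / 180)))
}

with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic region
#'
#' Collects every knob of the generator: tract counts per urbanicity class,
#' block counts and the log-normal block-population model, the fractions of
#' tracts planted into each ground-truth role, the partial-coverage fractions
#' (one above and one below the access fraction), the low-vehicle and
#' degenerate-tract counts, and the metro layout.
#'
#' @param n_urban,n_suburban,n_rural Tract counts per urbanicity class.
#' @param blocks_min,blocks_max Blocks per tract (uniform over the range).
#' @param block_pop_median,block_pop_sdlog Log-normal block population:
#'   median persons per block and dispersion on the log scale.
#' @param block_pop_equal All blocks get exactly `block_pop_median` persons
#'   (makes partial-coverage fractions exact for round multiples).
#' @param planted_desert_fraction Fraction of regular tracts planted to meet
#'   *both* desert criteria.
#' @param low_access_only_fraction Fraction planted low-access but not
#'   low-income.
#' @param low_income_covered_fraction Fraction planted low-income but fully
#'   covered.
#' @param partial_high,partial_low Outside-population fractions used for
#'   partial-coverage tracts above, respectively below, the access fraction.
#' @param partial_share Probability that an eligible tract uses partial
#'   coverage rather than all-or-nothing coverage.
#' @param low_vehicle_fraction Fraction of regular tracts given fewer than
#'   100 car owners (0.5-mile radius override).
#' @param car_missing_prob Probability that a non-override tract's car-owner
#'   count is missing (no override on missing).
#' @param income_arm_drop_prob Probability that one income field is dropped
#'   in a truth-preserving way (exercises the one-arm-missing rule).
#' @param n_zero_pop Zero-population tracts appended to the region.
#' @param n_missing_income Fully-covered, non-low-income tracts whose income
#'   fields are both blanked (truth: unclassified).
#' @param n_metros,metro_median_income Metro areas ringing the region; the
#'   i-th metro's median income is `metro_median_income * (1 + 0.15 (i-1))`.
#' @param n_states Tracts are dealt round-robin across this many state codes.
#' @param seed Integer seed; the same spec and seed give identical regions.
#' @return A `region_spec` object.
#' @export
region_spec <- function(n_urban = 6L, n_suburban = 6L, n_rural = 6L,
                        blocks_min = 4L, blocks_max = 10L,
                        block_pop_median = 400, block_pop_sdlog = 0.6,
                        block_pop_equal = FALSE,
                        planted_desert_fraction = 0.2,
                        low_access_only_fraction = 0.15,
                        low_income_covered_fraction = 0.2,
                        partial_high = 0.5, partial_low = 0.25,
                        partial_share = 0.4,
                        low_vehicle_fraction = 0.1,
                        car_missing_prob = 0.1,
                        income_arm_drop_prob = 0.15,
                        n_zero_pop = 0L, n_missing_income = 0L,
                        n_metros = 2L, metro_median_income = 62000,
                        n_states = 2L, seed = 1L) {
  spec <- as.list(environment())
  fracs <- c("planted_desert_fraction", "low_access_only_fraction",
             "low_income_covered_fraction", "partial_high", "partial_low",
             "partial_share", "low_vehicle_fraction", "car_missing_prob",
             "income_arm_drop_prob")
  for (f in fracs) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      stop("spec field `", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  role_sum <- spec$planted_desert_fraction + spec$low_access_only_fraction +
    spec$low_income_covered_fraction
  if (role_sum > 1) stop("planted role fractions exceed 1", call. = FALSE)
  if (spec$blocks_min < 1L || spec$blocks_max < spec$blocks_min) {
    stop("need 1 <= blocks_min <= blocks_max", call. = FALSE)
  }
  if (spec$n_urban + spec$n_suburban + spec$n_rural < 1L) {
    stop("need at least one regular tract", call. = FALSE)
  }
  structure(spec, class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec>", x$n_urban, "urban /", x$n_suburban, "suburban /",
      x$n_rural, "rural tracts, seed", x$seed, "\n")
  invisible(x)
}

# pick a subset of blocks whose population share approximates `target_frac`,
# landing at least `margin` away from `access_fraction` on the side that
# `target_frac` itself lies on; errors when no subset achieves that.
choose_outside_blocks <- function(pops, target_frac, access_fraction,
                                  margin = 0.02) {
  n <- length(pops); total <- sum(pops)
  side_hi <- target_frac > access_fraction
  ok <- function(share) {
    if (side_hi) share >= access_fraction + margin
    else share <= access_fraction - margin
  }
  ord <- order(pops, decreasing = TRUE)
  chosen <- logical(n); s <- 0
  for (i in ord) {   # greedy: add while it moves the share toward target
    if (abs((s + pops[i]) / total - target_frac) <= abs(s / total - target_frac)) {
      chosen[i] <- TRUE; s <- s + pops[i]
    }
  }
  # nudge by single blocks if the greedy share fell on the wrong side
  repeat {
    if (ok(s / total) && any(chosen) && !all(chosen)) break
    if (side_hi) {
      add <- which(!chosen)
      if (length(add) == 0L) break
      i <- add[which.min(pops[add])]
      chosen[i] <- TRUE; s <- s + pops[i]
    } else {
      dropi <- which(chosen)
      if (length(dropi) == 0L) break
      i <- dropi[which.min(pops[dropi])]
      chosen[i] <- FALSE; s <- s - pops[i]
    }
    if (all(chosen) || !any(chosen)) break
  }
  if (!ok(s / total) || !any(chosen) || all(chosen)) {
    stop("infeasible partial-coverage fraction ", signif(target_frac, 3),
         " with ", n, " blocks: no subset lands at margin ", margin,
         " from the access fraction", call. = FALSE)
  }
  chosen
}

table1_demographics <- function() {
  # tract-level demographic distributions (mean, sd) the generator emulates,
  # for desert and non-desert tracts respectively
  list(
    prop_hs_or_less            = list(d = c(0.332, 0.104), o = c(0.276, 0.114)),
    prop_uninsured             = list(d = c(0.152, 0.112), o = c(0.0989, 0.0856)),
    prop_public_insurance      = list(d = c(0.419, 0.158), o = c(0.354, 0.129)),
    prop_limited_english       = list(d = c(0.0573, 0.0953), o = c(0.0307, 0.0678)),
    prop_ambulatory_disability = list(d = c(0.104, 0.0637), o = c(0.0834, 0.0497)),
    prop_age_65_plus           = list(d = c(0.150, 0.101), o = c(0.169, 0.088)),
    prop_nh_white              = list(d = c(0.455, 0.321), o = c(0.612, 0.293)),
    prop_nh_black              = list(d = c(0.191, 0.261), o = c(0.126, 0.204)),
    prop_nh_asian              = list(d = c(0.0329, 0.0703), o = c(0.0525, 0.098)),
    prop_nh_aian               = list(d = c(0.035, 0.0149), o = c(0.0051, 0.0278)),
    prop_hispanic              = list(d = c(0.120, 0.161), o = c(0.0797, 0.116))
  )
}

pharmacy_profiles <- function() {
  list(
    desert = list(ownership = c(independent = 0.412, chain = 0.561,
                                franchise = 0.010, government = 0.017),
                  services = c(immunization = 0.752, ada_accessible = 0.986,
                               multidose_packaging = 0.248,
                               emergency_24h = 0.279, walk_in_clinic = 0.136,
                               compounding = 0.585, dme = 0.745)),
    other = list(ownership = c(independent = 0.366, chain = 0.621,
                               franchise = 0.011, government = 0.002),
                 services = c(immunization = 0.806, ada_accessible = 0.988,
                              multidose_packaging = 0.200,
                              emergency_24h = 0.296, walk_in_clinic = 0.065,
                              compounding = 0.619, dme = 0.777))
  )
}

#' Generate a synthetic region with known ground truth
#'
#' Lays tracts out on a sparse grid, builds blocks, pharmacies and metros so
#' that every tract's density band, coverage status and income status are
#' forced with margin, and returns the expected verdict of every tract
#' alongside the data. The same spec and seed always produce an identical
#' region.
#'
#' @param spec A [region_spec()].
#' @param policy The [threshold_policy()] the truth is planted against.
#' @return A `synthetic_region`: list with `blocks`, `tracts`, `pharmacies`,
#'   `metros` (the standard entity tibbles), `truth` (tibble `tract_id`,
#'   `urbanicity`, `radius`, `prop_outside`, `low_income`, `low_access`,
#'   `verdict`), plus the `spec` and `policy` used.
#' @export
generate_region <- function(spec, policy = threshold_policy()) {
  stopifnot(inherits(spec, "region_spec"))
  validate_policy(policy)
  af <- policy$access_fraction
  if (spec$partial_share > 0) {
    if (spec$partial_high < af + 0.05) {
      stop("partial_high must exceed the access fraction by >= 0.05",
           call. = FALSE)
    }
    if (spec$partial_low > af - 0.05) {
      stop("partial_low must sit below the access fraction by >= 0.05",
           call. = FALSE)
    }
  }
  with_preserved_seed(spec$seed, generate_region_impl(spec, policy))
}

generate_region_impl <- function(spec, policy) {
  n_reg <- spec$n_urban + spec$n_suburban + spec$n_rural
  classes <- c(rep("urban", spec$n_urban), rep("suburban", spec$n_suburban),
               rep("rural", spec$n_rural))

  n_desert <- round(spec$planted_desert_fraction * n_reg)
  n_lao <- round(spec$low_access_only_fraction * n_reg)
  n_lic <- round(spec$low_income_covered_fraction * n_reg)
  if (n_desert + n_lao + n_lic > n_reg) {
    stop("planted role counts exceed the number of regular tracts",
         call. = FALSE)
  }
  roles <- c(rep("desert", n_desert), rep("low_access_only", n_lao),
             rep("low_income_covered", n_lic),
             rep("plain", n_reg - n_desert - n_lao - n_lic))
  roles <- roles[sample.int(n_reg)]          # spread roles across classes

  plain_idx <- which(roles == "plain")
  if (spec$n_missing_income > length(plain_idx)) {
    stop("n_missing_income exceeds the number of plain tracts", call. = FALSE)
  }
  missing_income <- rep(FALSE, n_reg)
  missing_income[plain_idx[seq_len(spec$n_missing_income)]] <- TRUE

  n_lv <- round(spec$low_vehicle_fraction * n_reg)
  low_vehicle <- rep(FALSE, n_reg)
  low_vehicle[sample.int(n_reg, n_lv)] <- TRUE

  n_total <- n_reg + spec$n_zero_pop
  ncols <- ceiling(sqrt(n_total))
  lat0 <- 38; lon0 <- -96; spacing <- 30
  mpd <- miles_per_deg_lat()
  states <- c("WA", "OR", "CA", "AZ", "NM", "CO", "UT",
              "NV")[seq_len(max(1L, spec$n_states))]

  density_band <- function(class) {
    switch(class,
      urban = stats::runif(1, 1.1 * policy$density_urban_min,
                           2.0 * policy$density_urban_min),
      suburban = stats::runif(1, 1.5 * policy$density_rural_max,
                              0.8 * policy$density_urban_min),
      rural = stats::runif(1, 0.05 * policy$density_rural_max,
                           0.8 * policy$density_rural_max))
  }
  class_radius <- function(class) {
    switch(class, urban = policy$radius_urban,
           suburban = policy$radius_suburban, rural = policy$radius_rural)
  }

  blocks <- list(); tracts <- list(); pharmacies <- list(); truth <- list()
  demo <- table1_demographics()
  prof <- pharmacy_profiles()
  ph_id <- 0L

  place_blocks <- function(ctr_lat, ctr_lon, dists, prefix) {
    bearings <- stats::runif(length(dists), 0, 2 * pi)
    pts <- offset_point(ctr_lat, ctr_lon, dists, bearings)
    tibble(block_id = sprintf("%s-B%02d", prefix, seq_along(dists)),
           lat = pts$lat, lon = pts$lon)
  }
  make_pharmacy <- function(lat, lon, tract_id, group) {
    ph_id <<- ph_id + 1L
    p <- prof[[group]]
    own <- sample(ownership_levels, 1L, prob = p$ownership)
    flags <- lapply(service_flags, function(f) {
      if (stats::runif(1) < 0.02) NA else stats::runif(1) < p$services[[f]]
    })
    names(flags) <- service_flags
    c(list(pharmacy_id = sprintf("P%04d", ph_id), lat = lat, lon = lon,
           ownership = own, tract_id = tract_id), flags)
  }

  for (i in seq_len(n_total)) {
    row <- (i - 1L) %/% ncols; col <- (i - 1L) %% ncols
    ctr_lat <- lat0 + row * spacing / mpd
    ctr_lon <- lon0 + col * spacing / (mpd * cos(ctr_lat * pi / 180))
    tid <- sprintf("T%03d", i)
    state <- states[(i - 1L) %% length(states) + 1L]

    if (i > n_reg) {                               # zero-population tract
      nb <- spec$blocks_min
      bl <- place_blocks(ctr_lat, ctr_lon, stats::runif(nb, 0, 2), tid)
      bl$tract_id <- tid; bl$population <- 0L
      blocks[[i]] <- bl
      tracts[[i]] <- tibble(
        tract_id = tid, state = state, land_area = 5,
        population = 0L, median_income = NA_real_,
        prop_below_fpl = NA_real_, car_owner_count = NA_integer_)
      truth[[i]] <- tibble(tract_id = tid, urbanicity = NA_character_,
                           radius = NA_real_, prop_outside = NA_real_,
                           low_income = NA, low_access = NA,
                           verdict = "unclassified_zero_pop")
      next
    }

    class <- classes[i]; role <- roles[i]
    nb <- if (spec$blocks_min == spec$blocks_max) spec$blocks_min
          else sample(spec$blocks_min:spec$blocks_max, 1L)
    pops <- if (spec$block_pop_equal) rep(as.integer(spec$block_pop_median), nb)
            else pmax(1L, as.integer(round(stats::rlnorm(
              nb, log(spec$block_pop_median), spec$block_pop_sdlog))))
    pop <- sum(pops)
    land_area <- pop / density_band(class)

    radius <- if (low_vehicle[i]) {
      if (policy$low_vehicle_mode == "min") {
        min(policy$radius_low_vehicle, class_radius(class))
      } else policy$radius_low_vehicle
    } else class_radius(class)

    # coverage geometry and access truth
    wants_low_access <- role %in% c("desert", "low_access_only")
    partial <- stats::runif(1) < spec$partial_share && nb >= 2L
    if (wants_low_access && partial) {
      outside <- choose_outside_blocks(pops, spec$partial_high,
                                       policy$access_fraction)
    } else if (wants_low_access) {
      outside <- rep(TRUE, nb)
    } else if (partial) {
      outside <- tryCatch(
        choose_outside_blocks(pops, spec$partial_low,
                              policy$access_fraction),
        error = function(e) rep(FALSE, nb))
    } else {
      outside <- rep(FALSE, nb)
    }
    has_pharmacy <- !all(outside)
    dists <- ifelse(outside, stats::runif(nb, 1.05 * radius, 1.15 * radius),
                    stats::runif(nb, 0, 0.85 * radius))
    bl <- place_blocks(ctr_lat, ctr_lon, dists, tid)
    bl$tract_id <- tid; bl$population <- pops
    blocks[[i]] <- bl
    prop_outside <- sum(pops[outside]) / pop
    low_access <- if (policy$access_strict) prop_outside > policy$access_fraction
                  else prop_outside >= policy$access_fraction
    if (wants_low_access && !low_access) {
      stop("internal: planted low-access tract failed its own margin check",
           call. = FALSE)
    }

    # income truth with margin
    low_income <- role %in% c("desert", "low_income_covered")
    metro_median <- NA_real_   # filled after metros are laid out; use base
    fpl_arm_true <- low_income && stats::runif(1) < 0.5
    fpl <- if (!low_income) stats::runif(1, 0.02, policy$fpl_threshold - 0.02)
           else if (fpl_arm_true)
             stats::runif(1, policy$fpl_threshold + 0.02,
                          min(1, policy$fpl_threshold + 0.25))
           else stats::runif(1, 0.02, policy$fpl_threshold - 0.02)
    rel <- if (!low_income) stats::runif(1, policy$metro_income_ratio + 0.02, 1.4)
           else if (fpl_arm_true) stats::runif(1, policy$metro_income_ratio + 0.02, 1.4)
           else stats::runif(1, 0.5, policy$metro_income_ratio - 0.02)
    # `rel` is the tract income as a multiple of its nearest metro's median;
    # converted to dollars once metros exist (below)

    car <- if (low_vehicle[i]) sample(0:(policy$low_vehicle_count - 1L), 1L)
           else if (stats::runif(1) < spec$car_missing_prob) NA_integer_
           else max(policy$low_vehicle_count + 50L, as.integer(round(0.4 * pop)))

    tracts[[i]] <- tibble(
      tract_id = tid, state = state, land_area = land_area,
      population = as.integer(pop), median_income = rel,  # placeholder scale
      prop_below_fpl = fpl, car_owner_count = car)

    if (has_pharmacy) {
      grp <- if (role == "desert") "desert" else "other"
      pharmacies[[length(pharmacies) + 1L]] <-
        make_pharmacy(ctr_lat, ctr_lon, tid, grp)
    }

    verdict <- if (missing_income[i]) "unclassified_no_income"
               else if (low_income && low_access) "desert"
               else if (low_access) "low_access_only"
               else "not_desert"
    truth[[i]] <- tibble(tract_id = tid, urbanicity = class, radius = radius,
                         prop_outside = prop_outside,
                         low_income = if (missing_income[i]) NA else low_income,
                         low_access = low_access, verdict = verdict)
  }

  blocks <- bind_rows(blocks)[, c("block_id", "tract_id", "lat", "lon",
                                  "population")]
  tracts <- bind_rows(tracts)
  truth <- bind_rows(truth)

  # metros ring the region at >= 60 miles from the nearest grid corner
  span_rows <- ceiling(n_total / ncols)
  metro_pts <- list(
    c(lat0 - 60 / mpd, lon0 - 60 / (mpd * cos(lat0 * pi / 180))),
    c(lat0 + (span_rows * spacing + 60) / mpd,
      lon0 + (ncols * spacing + 60) / (mpd * cos(lat0 * pi / 180))),
    c(lat0 - 60 / mpd, lon0 + (ncols * spacing + 60) /
        (mpd * cos(lat0 * pi / 180))),
    c(lat0 + (span_rows * spacing + 60) / mpd,
      lon0 - 60 / (mpd * cos(lat0 * pi / 180))))
  nm <- max(1L, min(spec$n_metros, length(metro_pts)))
  metros <- tibble(
    metro_id = sprintf("M%02d", seq_len(nm)),
    lat = vapply(metro_pts[seq_len(nm)], `[`, 0, 1L),
    lon = vapply(metro_pts[seq_len(nm)], `[`, 0, 2L),
    median_income = spec$metro_median_income * (1 + 0.15 * (seq_len(nm) - 1L)))

  # convert the income multiple into dollars against each tract's nearest
  # metro (the same population-weighted-center rule the classifier uses)
  centers <- tract_centers(blocks)
  centers <- centers[match(tracts$tract_id, centers$tract_id), ]
  m <- metros[order(metros$metro_id), ]
  nearest_median <- vapply(seq_len(nrow(tracts)), function(i) {
    d <- great_circle_miles(centers$lat[i], centers$lon[i], m$lat, m$lon)
    m$median_income[which.min(d)]
  }, 0)
  tracts$median_income <- round(tracts$median_income * nearest_median)

  # blank income fields for planted-unclassified tracts; drop one arm
  # (truth-preserving) for a random subset of the rest
  reg <- seq_len(n_reg)
  tracts$median_income[tracts$population == 0L] <- NA_real_
  tracts$prop_below_fpl[tracts$population == 0L] <- NA_real_
  mi_ids <- truth$tract_id[truth$verdict == "unclassified_no_income"]
  tracts$median_income[tracts$tract_id %in% mi_ids] <- NA_real_
  tracts$prop_below_fpl[tracts$tract_id %in% mi_ids] <- NA_real_
  for (i in reg) {
    if (tracts$tract_id[i] %in% mi_ids) next
    if (stats::runif(1) >= spec$income_arm_drop_prob) next
    li <- truth$low_income[truth$tract_id == tracts$tract_id[i]]
    fpl_true <- !is.na(tracts$prop_below_fpl[i]) &&
      tracts$prop_below_fpl[i] >= policy$fpl_threshold
    if (isTRUE(li) && fpl_true) {
      tracts$median_income[i] <- NA_real_          # FPL arm alone still TRUE
    } else if (isTRUE(li) && !fpl_true) {
      tracts$prop_below_fpl[i] <- NA_real_         # income arm alone TRUE
    } else if (isFALSE(li)) {
      if (stats::runif(1) < 0.5) tracts$median_income[i] <- NA_real_
      else tracts$prop_below_fpl[i] <- NA_real_    # either arm alone FALSE
    }
  }

  # demographic proportions drawn from desert / non-desert distributions
  is_desert <- truth$verdict[match(tracts$tract_id, truth$tract_id)] == "desert"
  for (ch in names(demo)) {
    par <- demo[[ch]]
    v <- ifelse(is_desert,
                stats::rnorm(nrow(tracts), par$d[1], par$d[2]),
                stats::rnorm(nrow(tracts), par$o[1], par$o[2]))
    tracts[[ch]] <- pmin(1, pmax(0, v))
  }

  pharmacies <- if (length(pharmacies)) {
    bind_rows(purrr::map(pharmacies, as_tibble))
  } else {
    tibble(pharmacy_id = character(), lat = double(), lon = double(),
           ownership = character(), tract_id = character())
  }

  structure(list(blocks = blocks, tracts = tracts, pharmacies = pharmacies,
                 metros = metros, truth = truth, spec = spec,
                 policy = policy),
            class = "synthetic_region")
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat("<synthetic_region>", nrow(x$tracts), "tracts,", nrow(x$blocks),
      "blocks,", nrow(x$pharmacies), "pharmacies,", nrow(x$metros),
      "metros\n")
  print(table(x$truth$verdict))
  invisible(x)
}

#' Add one pharmacy to a synthetic region
#'
#' Places a pharmacy at a block centroid of the tract (default: its first
#' block in `block_id` order) or at the tract's population-weighted center,
#' leaves every other entity untouched, and recomputes the perturbed tract's
#' access truth by brute-force distances so the region's `truth` stays
#' consistent.
#'
#' @param region A `synthetic_region`.
#' @param tract_id Tract receiving the pharmacy.
#' @param placement `"at_block_centroid"` or `"at_tract_center"`.
#' @param block_id Optional block for `"at_block_centroid"`.
#' @return The perturbed `synthetic_region`.
#' @export
perturb_add_pharmacy <- function(region, tract_id,
                                 placement = c("at_block_centroid",
                                               "at_tract_center"),
                                 block_id = NULL) {
  stopifnot(inherits(region, "synthetic_region"))
  placement <- match.arg(placement)
  if (!tract_id %in% region$tracts$tract_id) {
    stop("unknown tract: ", tract_id, call. = FALSE)
  }
  bl <- region$blocks[region$blocks$tract_id == tract_id, ]
  if (placement == "at_block_centroid") {
    bl <- bl[order(bl$block_id), ]
    if (!is.null(block_id)) bl <- bl[bl$block_id == block_id, ]
    if (nrow(bl) == 0L) stop("no such block in tract", call. = FALSE)
    lat <- bl$lat[1L]; lon <- bl$lon[1L]
  } else {
    ctr <- tract_centers(region$blocks[region$blocks$tract_id == tract_id, ])
    lat <- ctr$lat; lon <- ctr$lon
  }
  new_id <- sprintf("P-ADD%03d", nrow(region$pharmacies) + 1L)
  new_row <- tibble(pharmacy_id = new_id, lat = lat, lon = lon,
                    ownership = "independent", tract_id = tract_id)
  for (f in service_flags) new_row[[f]] <- TRUE
  region$pharmacies <- bind_rows(region$pharmacies, new_row)

  # brute-force refresh of the perturbed tract's access truth
  ti <- which(region$truth$tract_id == tract_id)
  if (!region$truth$verdict[ti] %in% c("unclassified_zero_pop",
                                       "unclassified_no_income")) {
    r <- region$truth$radius[ti]
    blk <- region$blocks[region$blocks$tract_id == tract_id, ]
    live <- blk$population > 0
    covered <- vapply(which(live), function(j) {
      d <- great_circle_miles(blk$lat[j], blk$lon[j],
                              region$pharmacies$lat, region$pharmacies$lon)
      any(d < r)
    }, NA)
    outside <- sum(blk$population[live][!covered])
    prop <- outside / sum(blk$population)
    pol <- region$policy
    low_access <- if (pol$access_strict) prop > pol$access_fraction
                  else prop >= pol$access_fraction
    region$truth$prop_outside[ti] <- prop
    region$truth$low_access[ti] <- low_access
    li <- region$truth$low_income[ti]
    region$truth$verdict[ti] <-
      if (isTRUE(li) && low_access) "desert"
      else if (low_access) "low_access_only"
      else "not_desert"
  }
  region
}

#' Write a synthetic region to a directory of CSV files
#'
#' Emits `blocks.csv`, `tracts.csv`, `pharmacies.csv`, `metros.csv` and
#' `truth.csv`, readable back with the package readers.
#'
#' @param region A `synthetic_region`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_region <- function(region, dir) {
  stopifnot(inherits(region, "synthetic_region"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(region$blocks, file.path(dir, "blocks.csv"), na = "")
  readr::write_csv(region$tracts, file.path(dir, "tracts.csv"), na = "")
  readr::write_csv(region$pharmacies, file.path(dir, "pharmacies.csv"),
                   na = "")
  readr::write_csv(region$metros, file.path(dir, "metros.csv"), na = "")
  readr::write_csv(region$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
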