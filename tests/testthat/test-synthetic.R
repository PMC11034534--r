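test_that("planted desert count is exact and generation is deterministic", {
  spec <- region_spec(n_urban = 17L, n_suburban = 17L, n_rural = 16L,
                      planted_desert_fraction = 0.2, seed = 7L)
  r1 <- generate_region(spec)
  expect_equal(sum(r1$truth$verdict == "desert"), 10L)   # 0.2 x 50 tracts
  r2 <- generate_region(spec)
  expect_identical(r1$blocks, r2$blocks)
  expect_identical(r1$tracts, r2$tracts)
  expect_identical(r1$pharmacies, r2$pharmacies)
  expect_identical(r1$truth, r2$truth)
  # truth covers every generated tract
  expect_setequal(r1$truth$tract_id, r1$tracts$tract_id)
})

test_that("generated densities land strictly inside the intended band", {
  region <- standard_region()
  pol <- region$policy
  d <- region$tracts$population / region$tracts$land_area
  class <- region$truth$urbanicity[match(region$tracts$tract_id,
                                         region$truth$tract_id)]
  expect_true(all(d[which(class == "urban")] > pol$density_urban_min))
  expect_true(all(d[which(class == "suburban")] > pol$density_rural_max &
                    d[which(class == "suburban")] < pol$density_urban_min))
  expect_true(all(d[which(class == "rural")] < pol$density_rural_max))
})

test_that("no generated block sits within 5% of its radius boundary", {
  region <- standard_region()
  for (i in seq_len(nrow(region$truth))) {
    tr <- region$truth[i, ]
    if (is.na(tr$radius)) next
    bl <- region$blocks[region$blocks$tract_id == tr$tract_id, ]
    ph <- region$pharmacies
    if (nrow(ph) == 0) next
    dmin <- vapply(seq_len(nrow(bl)), function(j) {
      min(great_circle_miles(bl$lat[j], bl$lon[j], ph$lat, ph$lon))
    }, 0)
    in_margin <- dmin > 0.951 * tr$radius & dmin < 1.049 * tr$radius
    expect_false(any(in_margin), info = tr$tract_id)
  }
})

test_that("partial coverage with equal blocks yields the exact fraction", {
  spec <- region_spec(n_urban = 4L, n_suburban = 0L, n_rural = 0L,
                      blocks_min = 4L, blocks_max = 4L,
                      block_pop_equal = TRUE,
                      planted_desert_fraction = 1,
                      low_access_only_fraction = 0,
                      low_income_covered_fraction = 0,
                      partial_share = 1, partial_high = 0.5,
                      low_vehicle_fraction = 0, car_missing_prob = 0,
                      seed = 5L)
  region <- generate_region(spec)
  pol <- region$policy
  for (tid in region$tracts$tract_id) {
    tr <- region$tracts[region$tracts$tract_id == tid, ]
    bl <- region$blocks[region$blocks$tract_id == tid, ]
    acc <- tract_access(tr, bl, region$pharmacies, 1.0, pol)
    expect_equal(acc$prop_outside, 0.5, info = tid)
  }
})

test_that("income values are planted with margin on both criteria", {
  region <- standard_region()
  pol <- region$policy
  tr <- region$tracts
  li <- region$truth$low_income[match(tr$tract_id, region$truth$tract_id)]
  # the poverty arm never sits inside +-0.02 of the threshold
  fpl <- tr$prop_below_fpl[!is.na(tr$prop_below_fpl)]
  expect_true(all(abs(fpl - pol$fpl_threshold) >= 0.02 - 1e-9))
  # tracts planted not-low-income fail both arms
  centers <- tract_centers(region$blocks)
  for (i in which(!is.na(li) & !li)) {
    expect_true(is.na(tr$prop_below_fpl[i]) ||
                  tr$prop_below_fpl[i] < pol$fpl_threshold)
    if (!is.na(tr$median_income[i])) {
      ctr <- centers[centers$tract_id == tr$tract_id[i], ]
      m <- region$metros[order(region$metros$metro_id), ]
      d <- great_circle_miles(ctr$lat, ctr$lon, m$lat, m$lon)
      expect_gte(tr$median_income[i],
                 pol$metro_income_ratio * m$median_income[which.min(d)])
    }
  }
})

test_that("infeasible specs error before emission", {
  expect_error(region_spec(planted_desert_fraction = 1.5), "\\[0, 1\\]")
  expect_error(region_spec(planted_desert_fraction = 0.6,
                           low_access_only_fraction = 0.6), "exceed 1")
  expect_error(generate_region(region_spec(partial_high = 0.35)),
               "partial_high")
  expect_error(generate_region(region_spec(partial_low = 0.32)),
               "partial_low")
  expect_error(generate_region(region_spec(n_missing_income = 100L)),
               "n_missing_income")
  # a partial fraction unreachable with the block count
  expect_error(
    desertmap:::choose_outside_blocks(c(500, 500), target_frac = 0.25,
                                      access_fraction = 1 / 3),
    "infeasible")
})

test_that("adding a pharmacy flips planted deserts and spares the rest", {
  region <- standard_region()
  cl0 <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                         region$metros, region$policy)
  desert_id <- region$truth$tract_id[region$truth$verdict == "desert"][1]
  pert <- region
  for (bid in region$blocks$block_id[region$blocks$tract_id == desert_id]) {
    pert <- perturb_add_pharmacy(pert, desert_id, "at_block_centroid", bid)
  }
  # with a pharmacy on every block centroid, access truth flips to covered
  expect_equal(pert$truth$verdict[pert$truth$tract_id == desert_id],
               "not_desert")
  cl1 <- classify_tracts(pert$blocks, pert$tracts, pert$pharmacies,
                         pert$metros, region$policy)
  expect_equal(as.character(cl1$verdict[cl1$tract_id == desert_id]),
               "not_desert")
  # unrelated tracts keep their verdicts (tracts are radius-isolated)
  others <- cl1$tract_id != desert_id
  expect_identical(cl1$verdict[others], cl0$verdict[others])
  # a pharmacy far outside all radii changes nothing
  far <- region
  far$pharmacies <- dplyr::bind_rows(
    far$pharmacies,
    tibble::tibble(pharmacy_id = "PFAR", lat = 20, lon = -60,
                   ownership = "chain", tract_id = NA_character_))
  cl2 <- classify_tracts(far$blocks, far$tracts, far$pharmacies,
                         far$metros, region$policy)
  expect_identical(cl2$verdict, cl0$verdict)
  expect_error(perturb_add_pharmacy(region, "nope"), "unknown tract")
})

test_that("written regions survive the round trip through CSV", {
  region <- standard_region()
  dir <- withr::local_tempdir()
  write_region(region, dir)
  expect_setequal(list.files(dir),
                  c("blocks.csv", "tracts.csv", "pharmacies.csv",
                    "metros.csv", "truth.csv"))
  blocks <- read_blocks(file.path(dir, "blocks.csv"))
  tracts <- read_tracts(file.path(dir, "tracts.csv"), blocks = blocks)
  pharmacies <- read_pharmacies(file.path(dir, "pharmacies.csv"))
  metros <- read_metros(file.path(dir, "metros.csv"))
  cl <- classify_tracts(blocks, tracts, pharmacies, metros, region$policy)
  expect_identical(
    as.character(cl$verdict[match(region$truth$tract_id, cl$tract_id)]),
    region$truth$verdict)
})
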