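test_that("urbanicity boundaries: 5000 is urban, below 1000 is rural", {
  policy <- default_policy
  tr <- tibble::tibble(population = c(5000L, 999L, 2500L),
                       land_area = 1)
  expect_equal(classify_urbanicity(tr, policy),
               c("urban", "rural", "suburban"))
  expect_error(classify_urbanicity(tibble::tibble(population = 1L,
                                                  land_area = 0), policy),
               "land_area")
})

test_that("radius policy: class radii and the low-vehicle override", {
  policy <- default_policy
  tr <- tibble::tibble(car_owner_count = c(5000L, 99L, NA, 100L))
  urb <- c("rural", "urban", "suburban", "urban")
  expect_equal(radius_for(tr, urb, policy), c(10, 0.5, 5, 1))
  # "min" mode takes the smaller of override and class radius
  pol_min <- threshold_policy(low_vehicle_mode = "min")
  expect_equal(radius_for(tr, urb, pol_min), c(10, 0.5, 5, 1))
  expect_equal(radius_for(tibble::tibble(car_owner_count = 50L), "rural",
                          pol_min), 0.5)
})

test_that("low-income indicator: inclusive FPL arm, strict relative arm", {
  policy <- default_policy
  metros <- tibble::tibble(metro_id = "M1", lat = 41, lon = -100,
                           median_income = 60000)
  bl <- tibble::tibble(block_id = "B1", tract_id = "T1", lat = 40,
                       lon = -100, population = 10L)
  mk <- function(fpl, inc) tibble::tibble(
    tract_id = "T1", prop_below_fpl = fpl, median_income = inc)

  expect_true(is_low_income(mk(0.20, 70000), metros, policy, bl))   # at 20%
  expect_true(is_low_income(mk(0.10, 46400), metros, policy, bl))   # < 48000
  expect_false(is_low_income(mk(0.10, 48000), metros, policy, bl))  # exactly 80%
  expect_true(is.na(is_low_income(mk(NA, NA), metros, policy, bl)))
  # one arm missing: evaluate the known arm alone
  expect_true(is_low_income(mk(0.25, NA), metros, policy, bl))
  expect_false(is_low_income(mk(NA, 59000), metros, policy, bl))
  expect_error(is_low_income(mk(0.1, 50000), metros[0, ], policy, bl),
               "metropolitan")
})

test_that("nearest metro: distance rule with lexicographic tie-break", {
  bl <- tibble::tibble(block_id = "B1", tract_id = "T1", lat = 40,
                       lon = -100, population = 10L)
  tr <- tibble::tibble(tract_id = "T1")
  m1 <- tibble::tibble(metro_id = "M1", lat = 41, lon = -100,
                       median_income = 1)
  expect_equal(nearest_metro(tr, bl, m1)$metro_id, "M1")
  # 10-mile metro beats 40-mile metro
  deg <- 1 / (3958.8 * pi / 180)
  m2 <- tibble::tibble(metro_id = c("MFAR", "MNEAR"),
                       lat = c(40 + 40 * deg, 40 + 10 * deg), lon = -100,
                       median_income = c(1, 2))
  expect_equal(nearest_metro(tr, bl, m2)$metro_id, "MNEAR")
  # exact tie: lexicographically smaller id wins
  m3 <- tibble::tibble(metro_id = c("MB", "MA"),
                       lat = c(40 + 10 * deg, 40 - 10 * deg), lon = -100,
                       median_income = c(1, 2))
  expect_equal(nearest_metro(tr, bl, m3)$metro_id, "MA")
})

test_that("verdicts partition the tracts and follow precedence rules", {
  region <- standard_region()
  cl <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                        region$metros, region$policy)
  expect_equal(nrow(cl), nrow(region$tracts))
  expect_false(any(is.na(cl$verdict)))
  expect_equal(sum(table(cl$verdict)), nrow(region$tracts))
  # desert <=> low income AND low access, for classified tracts
  classified <- cl$verdict %in% c("desert", "low_access_only", "not_desert")
  expect_equal(cl$verdict[classified] == "desert",
               (cl$low_income & cl$low_access)[classified])
  expect_equal(cl$verdict[classified] == "low_access_only",
               (cl$low_access & !cl$low_income)[classified])
  # zero population wins over everything; missing income over access
  expect_equal(as.character(cl$verdict[cl$population == 0]),
               rep("unclassified_zero_pop", sum(cl$population == 0)))
  no_inc <- cl$verdict == "unclassified_no_income"
  expect_true(all(cl$population[no_inc] > 0))
  expect_true(all(is.na(cl$low_income[no_inc])))
})

test_that("verdicts equal planted truth across seeds and conditions", {
  for (seed in c(2, 5, 8)) {
    region <- cached_region(
      paste0("truth", seed),
      region_spec(n_urban = 6L, n_suburban = 6L, n_rural = 6L,
                  n_zero_pop = 1L, n_missing_income = 1L,
                  partial_share = 0.6, low_vehicle_fraction = 0.2,
                  seed = seed))
    cl <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                          region$metros, region$policy)
    got <- as.character(cl$verdict[match(region$truth$tract_id, cl$tract_id)])
    expect_identical(got, region$truth$verdict, info = paste("seed", seed))
  }
})

test_that("density thresholds act only through the urbanicity channel", {
  region <- standard_region()
  policy2 <- threshold_policy(density_urban_min = 1200,
                              density_rural_max = 1000)
  cl1 <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                         region$metros, region$policy)
  cl2 <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                         region$metros, policy2)
  # suburban tracts (density in [1200, 5000)) became urban ...
  was_suburban <- which(cl1$urbanicity == "suburban")
  expect_true(all(cl2$urbanicity[was_suburban] == "urban"))
  # ... and only radius-mediated fields may differ; income is untouched
  expect_identical(cl1$low_income, cl2$low_income)
  same_radius <- which(cl1$radius_used == cl2$radius_used)
  expect_identical(cl1$prop_outside[same_radius],
                   cl2$prop_outside[same_radius])
  expect_identical(cl1$verdict[same_radius], cl2$verdict[same_radius])
})

test_that("access-only mode matches the gated desert and low-access sets", {
  for (seed in c(11, 21)) {
    region <- standard_region(seed)
    gated <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                             region$metros, region$policy)
    ungated <- classify_tracts(region$blocks, region$tracts,
                               region$pharmacies, region$metros,
                               region$policy, income_gate = FALSE)
    expect_setequal(
      gated$tract_id[gated$verdict %in% c("desert", "low_access_only")],
      ungated$tract_id[ungated$verdict == "low_access_only"])
    expect_false(any(ungated$verdict == "desert"))
    # the unclassified universe is identical in both modes
    expect_identical(
      gated$tract_id[grepl("unclassified", gated$verdict)],
      ungated$tract_id[grepl("unclassified", ungated$verdict)])
  }
})
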