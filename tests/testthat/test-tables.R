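# helpers to build comparison-table inputs directly, with exact counts
mk_classifications <- function(n_desert, n_other, pharmacies_per_tract = 0L) {
  n <- n_desert + n_other
  tibble::tibble(
    tract_id = sprintf("T%03d", seq_len(n)),
    state = "WA",
    urbanicity = rep(c("urban", "rural"), length.out = n),
    radius_used = 1, population = 1000L, population_outside = 0L,
    prop_outside = 0.1, low_income = FALSE, income_partial = FALSE,
    low_access = FALSE,
    n_pharmacies_in_tract = rep(pharmacies_per_tract, length.out = n),
    verdict = factor(c(rep("desert", n_desert), rep("not_desert", n_other)),
                     levels = verdict_levels))
}

test_that("generated income effect shows up and reaches significance", {
  region <- large_region()
  cl <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                        region$metros, region$policy)
  t1 <- build_population_table(region$tracts, cl, region$policy)
  fpl <- t1[t1$characteristic == "prop_below_fpl", ]
  expect_gt(fpl$desert_mean, fpl$other_mean)
  expect_lt(fpl$p_adjusted, region$policy$alpha)
  # demographics planted with a desert shift point the same way
  hs <- t1[t1$characteristic == "prop_hs_or_less", ]
  expect_gt(hs$desert_mean, hs$other_mean)
  # within-family percentages sum to 100 in each group
  for (fam in c("urbanicity", "pharmacies_per_tract")) {
    rows <- t1[t1$characteristic == fam, ]
    expect_equal(sum(rows$desert_pct), 100, tolerance = 1e-9)
    expect_equal(sum(rows$other_pct), 100, tolerance = 1e-9)
  }
})

test_that("pharmacies-per-tract bins put two pharmacies in the 2+ bin", {
  cl <- mk_classifications(4, 6, pharmacies_per_tract = c(0L, 1L, 2L, 5L))
  tracts <- tibble::tibble(tract_id = cl$tract_id, state = "WA",
                           land_area = 1, population = 1000L,
                           median_income = 50000, prop_below_fpl = 0.1,
                           car_owner_count = 500L)
  t1 <- build_population_table(tracts, cl, default_policy,
                               characteristics = "median_income")
  bins <- t1[t1$characteristic == "pharmacies_per_tract", ]
  # desert group tracts carry 0,1,2,5 pharmacies -> one tract in each of
  # "0" and "1", two tracts with >= 2
  expect_equal(bins$desert_n[bins$level == "0"], 1L)
  expect_equal(bins$desert_n[bins$level == "1"], 1L)
  expect_equal(bins$desert_n[bins$level == "2+"], 2L)
})

test_that("planted ownership skew is recovered with exact planted counts", {
  cl <- mk_classifications(30, 100)
  desert_ids <- cl$tract_id[cl$verdict == "desert"]
  other_ids <- cl$tract_id[cl$verdict == "not_desert"]
  mk_ph <- function(ids, n_indep, n_chain, prefix) {
    n <- n_indep + n_chain
    out <- tibble::tibble(
      pharmacy_id = paste0(prefix, seq_len(n)),
      lat = 40, lon = -100,
      ownership = c(rep("independent", n_indep), rep("chain", n_chain)),
      tract_id = rep(ids, length.out = n))
    for (f in service_flags) out[[f]] <- TRUE
    out
  }
  ph <- dplyr::bind_rows(mk_ph(desert_ids, 180, 120, "D"),   # 60% independent
                         mk_ph(other_ids, 300, 700, "O"))    # 30% independent
  t2 <- build_pharmacy_table(ph, cl, default_policy)
  own <- t2[t2$characteristic == "ownership", ]
  ind <- own[own$level == "independent", ]
  expect_equal(ind$desert_pct, 60)
  expect_equal(ind$other_pct, 30)
  expect_gt(ind$desert_pct, ind$other_pct)
  expect_lt(ind$p_adjusted, default_policy$alpha)
})

test_that("unknown service flags are excluded from that flag's contrast", {
  cl <- mk_classifications(2, 2)
  ph <- tibble::tibble(
    pharmacy_id = paste0("P", 1:4), lat = 40, lon = -100,
    ownership = "chain",
    tract_id = cl$tract_id)
  for (f in service_flags) ph[[f]] <- TRUE
  ph$walk_in_clinic <- c(TRUE, NA, FALSE, NA)   # one unknown per group
  t2 <- build_pharmacy_table(ph, cl, default_policy)
  walk <- t2[t2$characteristic == "walk_in_clinic", ]
  expect_equal(walk$desert_n[walk$level == "yes"] +
                 walk$desert_n[walk$level == "no"], 1L)
  expect_equal(walk$other_n[walk$level == "yes"] +
                 walk$other_n[walk$level == "no"], 1L)
})

test_that("a degenerate desert group skips tests with a reason", {
  cl <- mk_classifications(0, 10)
  ph <- tibble::tibble(
    pharmacy_id = paste0("P", 1:10), lat = 40, lon = -100,
    ownership = rep(c("chain", "independent"), 5),
    tract_id = cl$tract_id)
  for (f in service_flags) ph[[f]] <- TRUE
  t2 <- build_pharmacy_table(ph, cl, default_policy)
  own <- t2[t2$characteristic == "ownership", ]
  expect_true(all(own$desert_n == 0L))
  expect_true(all(is.na(own$p_raw)))
  expect_match(own$note[1], "skipped")
})

test_that("pharmacies outside any classified tract are reported, not tested", {
  cl <- mk_classifications(2, 2)
  ph <- tibble::tibble(
    pharmacy_id = paste0("P", 1:5), lat = 40, lon = -100,
    ownership = "chain",
    tract_id = c(cl$tract_id, NA))   # one unplaceable pharmacy
  for (f in service_flags) ph[[f]] <- TRUE
  t2 <- build_pharmacy_table(ph, cl, default_policy)
  ex <- attr(t2, "excluded")
  expect_equal(ex$n[ex$category == "unassigned"], 1L)
})

test_that("joint BH family spans both tables; per-table is available", {
  region <- standard_region()
  cl <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                        region$metros, region$policy)
  joint <- compare_groups(region$tracts, region$pharmacies, cl,
                          region$policy, blocks = region$blocks,
                          bh_family = "joint")
  per <- compare_groups(region$tracts, region$pharmacies, cl,
                        region$policy, blocks = region$blocks,
                        bh_family = "per_table")
  # raw p-values agree between modes
  expect_equal(joint$population$p_raw, per$population$p_raw)
  # joint adjustment equals the step-up reference over the pooled family
  fams <- dplyr::bind_rows(
    dplyr::distinct(joint$population, characteristic, p_raw),
    dplyr::distinct(joint$pharmacy, characteristic, p_raw))
  fams <- fams[!is.na(fams$p_raw), ]
  want <- ref_bh(fams$p_raw)
  got <- dplyr::bind_rows(
    dplyr::distinct(joint$population, characteristic, p_raw, p_adjusted),
    dplyr::distinct(joint$pharmacy, characteristic, p_raw, p_adjusted))
  got <- got[!is.na(got$p_raw), ]
  expect_equal(got$p_adjusted, want, tolerance = 1e-12)
})

test_that("a characteristic absent from the tract table is an error", {
  region <- standard_region()
  cl <- classify_tracts(region$blocks, region$tracts, region$pharmacies,
                        region$metros, region$policy)
  expect_error(build_population_table(region$tracts, cl, region$policy,
                                      characteristics = "prop_wizards"),
               "prop_wizards")
})
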