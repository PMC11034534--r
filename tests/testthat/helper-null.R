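# one null replicate for the FDR-calibration check: tract characteristics
# and group labels drawn independently, so every comparison-table row is a
# true null; returns the fraction of BH-significant rows.
null_replicate_rate <- function(n = 80L, policy = threshold_policy()) {
  verdict <- sample(c("desert", "not_desert"), n, replace = TRUE,
                    prob = c(0.3, 0.7))
  cl <- tibble::tibble(
    tract_id = sprintf("T%03d", seq_len(n)), state = "WA",
    urbanicity = sample(urbanicity_levels, n, replace = TRUE),
    radius_used = 1, population = 1000L, population_outside = 0L,
    prop_outside = stats::runif(n), low_income = FALSE,
    income_partial = FALSE, low_access = FALSE,
    n_pharmacies_in_tract = stats::rpois(n, 1),
    verdict = factor(verdict, levels = verdict_levels))
  tracts <- tibble::tibble(
    tract_id = cl$tract_id, state = "WA", land_area = 1,
    population = 1000L,
    median_income = stats::rnorm(n, 60000, 12000),
    prop_below_fpl = stats::rbeta(n, 2, 10),
    car_owner_count = 500L)
  for (ch in demographic_cols) tracts[[ch]] <- stats::rbeta(n, 2, 6)
  t1 <- build_population_table(tracts, cl, policy)
  rows <- dplyr::distinct(t1, characteristic, p_adjusted)
  mean(rows$p_adjusted < policy$alpha, na.rm = TRUE)
}
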