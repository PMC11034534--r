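# National and state roll-ups, and the end-to-end pipeline runner.

rollup_one <- function(classifications, tracts) {
  cl <- classifications %>%
    left_join(select(tracts, tract_id), by = "tract_id")
  counts <- table(cl$verdict)
  classified <- cl$verdict %in% c("desert", "low_access_only", "not_desert")
  pop_classified <- sum(cl$population[classified])
  pop_desert <- sum(cl$population[cl$verdict == "desert"])
  pop_low_access <- sum(cl$population[cl$verdict %in%
                                        c("desert", "low_access_only")])
  tibble(
    n_tracts = nrow(cl),
    n_desert = as.integer(counts[["desert"]]),
    n_low_access_only = as.integer(counts[["low_access_only"]]),
    n_not_desert = as.integer(counts[["not_desert"]]),
    n_unclassified_no_income = as.integer(counts[["unclassified_no_income"]]),
    n_unclassified_zero_pop = as.integer(counts[["unclassified_zero_pop"]]),
    n_low_access_total = as.integer(counts[["desert"]] +
                                      counts[["low_access_only"]]),
    population_classified = pop_classified,
    population_in_deserts = pop_desert,
    percent_population_in_deserts =
      if (pop_classified > 0) 100 * pop_desert / pop_classified else 0,
    population_low_access = pop_low_access,
    percent_population_low_access =
      if (pop_classified > 0) 100 * pop_low_access / pop_classified else 0)
}

#' National roll-up of tract classifications
#'
#' Verdict counts, population living in desert tracts, that population as a
#' percent of the classified population (tracts with a desert /
#' low-access-only / not-desert verdict), and the income-gate-off totals
#' (deserts plus low-access-only tracts — the low-access universe of the
#' sensitivity analysis).
#'
#' @param classifications Output of [classify_tracts()].
#' @param tracts Tract table (ids must cover the classifications).
#' @return One-row tibble of counts and percentages.
#' @export
national_rollup <- function(classifications, tracts) {
  rollup_one(classifications, tracts)
}

#' Per-state roll-up
#'
#' Same arithmetic as [national_rollup()], grouped by state. States with no
#' desert tracts appear with zero counts, never omitted; summing any count
#' column over states reproduces the national value.
#'
#' @inheritParams national_rollup
#' @return Tibble with one row per state, `state` first.
#' @export
state_summaries <- function(classifications, tracts) {
  classifications %>%
    group_by(state) %>%
    dplyr::group_modify(~ rollup_one(.x, tracts)) %>%
    ungroup() %>%
    arrange(state)
}

#' Run the full classification pipeline
#'
#' Reads the four entity tables, classifies every tract (and re-classifies
#' with the income gate disabled for the sensitivity layer), builds both
#' comparison tables, rolls up nationally and by state, and writes
#' `classified.csv`, `classified_access_only.csv`, `classified.geojson`,
#' `table1.csv`, `table2.csv`, `states.csv`, `national.csv` and
#' `manifest.json` into `out_dir`. Outputs are deterministic given the
#' inputs and the policy; the manifest records the package version, every
#' policy threshold and the md5 checksum of each input so two runs with equal
#' manifests are byte-identical.
#'
#' @param blocks_path,tracts_path,pharmacies_path,metros_path Input files
#'   (CSV or GeoJSON, see [read_blocks()]).
#' @param out_dir Output directory, created if needed.
#' @param policy A [threshold_policy()].
#' @param bh_family BH correction family, `"joint"` (default) or
#'   `"per_table"`.
#' @return Invisibly, a list with `classifications`, `sensitivity`,
#'   `tables`, `national`, `states`, `manifest`.
#' @export
run_pipeline <- function(blocks_path, tracts_path, pharmacies_path,
                         metros_path, out_dir,
                         policy = threshold_policy(),
                         bh_family = c("joint", "per_table")) {
  bh_family <- match.arg(bh_family)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  blocks <- stage("read_blocks", read_blocks(blocks_path))
  tracts <- stage("read_tracts", read_tracts(tracts_path, blocks = blocks))
  pharmacies <- stage("read_pharmacies", read_pharmacies(pharmacies_path))
  metros <- stage("read_metros", read_metros(metros_path))

  cl <- stage("classify",
              classify_tracts(blocks, tracts, pharmacies, metros, policy))
  cl_access <- stage("classify_access_only",
                     classify_tracts(blocks, tracts, pharmacies, metros,
                                     policy, income_gate = FALSE))
  tables <- stage("compare",
                  compare_groups(tracts, pharmacies, cl, policy,
                                 blocks = blocks, bh_family = bh_family))
  national <- stage("rollup", national_rollup(cl, tracts))
  states <- stage("rollup_states", state_summaries(cl, tracts))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(cl, file.path(out_dir, "classified.csv"), na = "")
  readr::write_csv(cl_access, file.path(out_dir, "classified_access_only.csv"),
                   na = "")
  write_classification_geojson(cl, tracts,
                               file.path(out_dir, "classified.geojson"),
                               blocks = blocks)
  readr::write_csv(tables$population, file.path(out_dir, "table1.csv"),
                   na = "")
  readr::write_csv(tables$pharmacy, file.path(out_dir, "table2.csv"),
                   na = "")
  readr::write_csv(states, file.path(out_dir, "states.csv"), na = "")
  readr::write_csv(national, file.path(out_dir, "national.csv"), na = "")

  inputs <- c(blocks = blocks_path, tracts = tracts_path,
              pharmacies = pharmacies_path, metros = metros_path)
  manifest <- list(
    package = "desertmap",
    version = as.character(utils::packageVersion("desertmap")),
    policy = unclass(policy),
    bh_family = bh_family,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(classifications = cl, sensitivity = cl_access,
                 tables = tables, national = national, states = states,
                 manifest = manifest))
}
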