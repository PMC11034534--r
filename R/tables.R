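# Desert vs non-desert comparison tables: tract-population characteristics
# and pharmacy characteristics, with BH-corrected tests.
#
# Group definition: the desert group is verdict == "desert"; the comparison
# group is every *classified* non-desert tract (not_desert or
# low_access_only). Unclassified tracts belong to neither group.

desert_group_ids <- function(classifications) {
  classifications$tract_id[classifications$verdict == "desert"]
}

nondesert_group_ids <- function(classifications) {
  classifications$tract_id[classifications$verdict %in%
                             c("not_desert", "low_access_only")]
}

# One continuous characteristic -> a single comparison row (unweighted
# tract-level mean and SD in each group, Welch or pooled t test).
continuous_row <- function(values_a, values_b, characteristic, variant) {
  tst <- tryCatch(
    two_sample_t(values_a, values_b, variant, characteristic),
    error = function(e) NULL)
  tibble(
    characteristic = characteristic, level = NA_character_,
    test = "t",
    desert_mean = mean(values_a, na.rm = TRUE),
    desert_sd = stats::sd(values_a, na.rm = TRUE),
    other_mean = mean(values_b, na.rm = TRUE),
    other_sd = stats::sd(values_b, na.rm = TRUE),
    desert_n = NA_integer_, desert_pct = NA_real_,
    other_n = NA_integer_, other_pct = NA_real_,
    statistic = if (is.null(tst)) NA_real_ else tst$statistic,
    df = if (is.null(tst)) NA_real_ else tst$df,
    p_raw = if (is.null(tst)) NA_real_ else tst$p_raw,
    note = if (is.null(tst)) "test skipped: undersized or degenerate group"
           else NA_character_)
}

# One categorical family -> one row per level sharing the family's single
# chi-square p-value; percentages are within-group (100 * count / group
# total over the family's levels).
categorical_rows <- function(counts, characteristic) {
  # counts: matrix, rows = levels, 2 columns = (desert, other)
  tst <- tryCatch(chi_square_independence(counts), error = function(e) NULL)
  tot <- colSums(counts)
  pct <- function(cnt, total) if (total > 0) 100 * cnt / total else NA_real_
  tibble(
    characteristic = characteristic, level = rownames(counts),
    test = "chi_square",
    desert_mean = NA_real_, desert_sd = NA_real_,
    other_mean = NA_real_, other_sd = NA_real_,
    desert_n = as.integer(counts[, 1L]),
    desert_pct = unname(vapply(counts[, 1L], pct, 0, total = tot[[1L]])),
    other_n = as.integer(counts[, 2L]),
    other_pct = unname(vapply(counts[, 2L], pct, 0, total = tot[[2L]])),
    statistic = if (is.null(tst)) NA_real_ else tst$statistic,
    df = if (is.null(tst)) NA_real_ else tst$df,
    p_raw = if (is.null(tst)) NA_real_ else tst$p_raw,
    note = if (is.null(tst)) "test skipped: degenerate table"
           else NA_character_)
}

# BH across a family of rows: each characteristic contributes one p-value to
# the family regardless of how many level rows display it.
adjust_rows <- function(rows, alpha) {
  fam <- rows %>%
    distinct(characteristic, p_raw) %>%
    filter(!is.na(p_raw))
  fam$p_adjusted <- bh_adjust(fam$p_raw)
  rows %>%
    left_join(fam, by = c("characteristic", "p_raw")) %>%
    mutate(significant = !is.na(p_adjusted) & p_adjusted < alpha)
}

#' Tract-population comparison table (desert vs non-desert)
#'
#' Categorical families: tract urbanicity and pharmacies-per-tract binned as
#' \{0, 1, 2+\}, as counts with within-group percents and a chi-square test.
#' Continuous characteristics (`prop_below_fpl`, `median_income`, and any
#' [demographic_cols] present on the tract table) are unweighted tract-level
#' means and SDs with a two-sample t test.
#'
#' @param tracts Tract table.
#' @param classifications Output of [classify_tracts()].
#' @param policy A [threshold_policy()].
#' @param characteristics Continuous columns to compare; default
#'   `prop_below_fpl`, `median_income` plus every demographic column present.
#' @param variant t-test variant, `"welch"` (default) or `"pooled"`.
#' @param adjust Apply BH within this table's rows (default). Set `FALSE`
#'   when the caller adjusts jointly across tables via [compare_groups()].
#' @return Tibble of comparison rows (one per continuous characteristic, one
#'   per level of each categorical family); when `adjust = TRUE` also
#'   `p_adjusted` and `significant` at the policy alpha.
#' @export
build_population_table <- function(tracts, classifications, policy,
                                   characteristics = NULL,
                                   variant = c("welch", "pooled"),
                                   adjust = TRUE) {
  variant <- match.arg(variant)
  if (is.null(characteristics)) {
    characteristics <- c("prop_below_fpl", "median_income",
                         intersect(demographic_cols, names(tracts)))
  }
  missing_chars <- setdiff(characteristics, names(tracts))
  if (length(missing_chars)) {
    stop("characteristic(s) absent from tract table: ",
         paste(missing_chars, collapse = ", "), call. = FALSE)
  }
  ids_a <- desert_group_ids(classifications)
  ids_b <- nondesert_group_ids(classifications)
  cl_a <- classifications[classifications$tract_id %in% ids_a, ]
  cl_b <- classifications[classifications$tract_id %in% ids_b, ]
  tr_a <- tracts[match(ids_a, tracts$tract_id), ]
  tr_b <- tracts[match(ids_b, tracts$tract_id), ]

  urb_counts <- cbind(
    desert = table(factor(cl_a$urbanicity, levels = urbanicity_levels)),
    other = table(factor(cl_b$urbanicity, levels = urbanicity_levels)))
  bin_pharm <- function(n) {
    cut(n, breaks = c(-0.5, 0.5, 1.5, Inf), labels = c("0", "1", "2+"))
  }
  ph_counts <- cbind(
    desert = table(bin_pharm(cl_a$n_pharmacies_in_tract)),
    other = table(bin_pharm(cl_b$n_pharmacies_in_tract)))

  rows <- bind_rows(
    categorical_rows(urb_counts, "urbanicity"),
    categorical_rows(ph_counts, "pharmacies_per_tract"),
    bind_rows(purrr::map(characteristics, function(ch) {
      continuous_row(tr_a[[ch]], tr_b[[ch]], ch, variant)
    })))
  if (adjust) rows <- adjust_rows(rows, policy$alpha)
  rows
}

#' Pharmacy comparison table (pharmacies in deserts vs non-deserts)
#'
#' Each pharmacy carries the verdict of its containing tract (its own
#' `tract_id` column, else the tract of the nearest block centroid).
#' Families: urbanicity of the pharmacy's tract (including an
#' `"na_no_population"` level for pharmacies in zero-population tracts),
#' ownership (4 levels), and each service flag as yes/no with unknown flags
#' excluded from that flag's counts and denominators. Pharmacies in no tract
#' or in unclassified tracts are excluded from every test and reported in the
#' `excluded` attribute.
#'
#' @inheritParams build_population_table
#' @param pharmacies Pharmacy table.
#' @param blocks Block table (needed when pharmacies lack `tract_id`).
#' @return Tibble of comparison rows; attribute `excluded` is a tibble of
#'   `category`/`n` for the unassigned / unclassified buckets.
#' @export
build_pharmacy_table <- function(pharmacies, classifications, policy,
                                 blocks = NULL, adjust = TRUE) {
  tract_of <- assign_pharmacy_tracts(pharmacies,
                                     if (is.null(blocks)) pharmacies[0, ]
                                     else blocks)
  cl <- classifications[match(tract_of, classifications$tract_id), ]
  group <- ifelse(is.na(tract_of) | is.na(cl$verdict), "unassigned",
           ifelse(cl$verdict == "desert", "desert",
           ifelse(cl$verdict %in% c("not_desert", "low_access_only"), "other",
                  "unclassified")))
  excluded <- tibble(category = c("unassigned", "unclassified_tract"),
                     n = c(sum(group == "unassigned"),
                           sum(group == "unclassified")))
  keep <- group %in% c("desert", "other")
  ph <- pharmacies[keep, ]
  grp <- factor(group[keep], levels = c("desert", "other"))
  urb <- as.character(cl$urbanicity[keep])
  urb[is.na(urb)] <- "na_no_population"

  urb_counts <- cbind(
    desert = table(factor(urb[grp == "desert"],
                          levels = c(urbanicity_levels, "na_no_population"))),
    other = table(factor(urb[grp == "other"],
                         levels = c(urbanicity_levels, "na_no_population"))))
  own_counts <- cbind(
    desert = table(factor(ph$ownership[grp == "desert"],
                          levels = ownership_levels)),
    other = table(factor(ph$ownership[grp == "other"],
                         levels = ownership_levels)))

  rows <- list(categorical_rows(urb_counts, "urbanicity"),
               categorical_rows(own_counts, "ownership"))
  for (f in service_flags) {
    v <- ph[[f]]
    counts <- cbind(
      desert = c(yes = sum(v[grp == "desert"], na.rm = TRUE),
                 no = sum(!v[grp == "desert"], na.rm = TRUE)),
      other = c(yes = sum(v[grp == "other"], na.rm = TRUE),
                no = sum(!v[grp == "other"], na.rm = TRUE)))
    rows[[f]] <- categorical_rows(counts, f)
  }
  rows <- bind_rows(rows)
  if (adjust) rows <- adjust_rows(rows, policy$alpha)
  attr(rows, "excluded") <- excluded
  rows
}

#' Build both comparison tables with a shared BH family
#'
#' The default corrects all rows of both tables as one BH family (one p-value
#' per characteristic family); `bh_family = "per_table"` corrects each table
#' separately.
#'
#' @inheritParams build_pharmacy_table
#' @param tracts Tract table.
#' @param bh_family `"joint"` (default) or `"per_table"`.
#' @return List with elements `population` and `pharmacy`, each a comparison
#'   tibble with `p_adjusted` and `significant`.
#' @export
compare_groups <- function(tracts, pharmacies, classifications, policy,
                           blocks = NULL, bh_family = c("joint", "per_table"),
                           variant = c("welch", "pooled")) {
  bh_family <- match.arg(bh_family)
  variant <- match.arg(variant)
  t1 <- build_population_table(tracts, classifications, policy,
                               variant = variant,
                               adjust = (bh_family == "per_table"))
  t2 <- build_pharmacy_table(pharmacies, classifications, policy,
                             blocks = blocks,
                             adjust = (bh_family == "per_table"))
  if (bh_family == "joint") {
    t1$table <- "population"; t2$table <- "pharmacy"
    both <- adjust_rows(bind_rows(t1, t2), policy$alpha)
    t1 <- both[both$table == "population",
               setdiff(names(both), "table")]
    ex <- attr(t2, "excluded")
    t2 <- both[both$table == "pharmacy", setdiff(names(both), "table")]
    attr(t2, "excluded") <- ex
  }
  list(population = t1, pharmacy = t2)
}
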