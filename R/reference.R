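#' Published national tabulations of pharmacy deserts (United States, 2022)
#'
#' Group counts from the published national tract-level pharmacy-desert
#' analysis, shipped as plain CSV: the population table's categorical
#' families (tract urbanicity, pharmacies per tract), the pharmacy table's
#' families (pharmacy-location urbanicity, ownership, service flags, with
#' group sizes 294 desert / 60 175 non-desert pharmacies), and the national
#' verdict counts (84 414 tracts). The printed within-group percentages (and,
#' for the pharmacy table, the printed adjusted p-values) ride along so the
#' package's percentage and chi-square machinery can be checked against
#' in-table arithmetic without any external download.
#'
#' @param table `"population"`, `"pharmacy"`, or `"national"`.
#' @return A tibble of the requested reference counts.
#' @examples
#' reference_counts("pharmacy")
#' @export
reference_counts <- function(table = c("population", "pharmacy", "national")) {
  table <- match.arg(table)
  file <- switch(table, population = "table1_counts.csv",
                 pharmacy = "table2_counts.csv",
                 national = "national_counts.csv")
  path <- system.file("extdata", "reference", file, package = "desertmap")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
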