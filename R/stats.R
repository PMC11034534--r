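# Group-contrast machinery: two-sample t tests, chi-square tests of
# independence, and Benjamini-Hochberg correction across the test family.

#' Two-sample t test
#'
#' Two-sided test of equal means. The Welch variant (default) uses the
#' Welch-Satterthwaite degrees of freedom and does not assume equal
#' variances; `"pooled"` is the classical equal-variance test. The two agree
#' exactly when group sizes and variances are equal.
#'
#' @param x,y Numeric samples for the two groups (`NA`s dropped).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param characteristic Optional name used in error messages.
#' @return List with `statistic`, `df`, `p_raw`.
#' @export
two_sample_t <- function(x, y, variant = c("welch", "pooled"),
                         characteristic = NULL) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  label <- if (is.null(characteristic)) "" else paste0(" for `", characteristic, "`")
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 non-missing values", label,
         call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      # degenerate null: identical constant samples carry no evidence
      return(list(statistic = 0, df = length(x) + length(y) - 2, p_raw = 1))
    }
    stop("both groups have zero variance", label, call. = FALSE)
  }
  fit <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_raw = fit$p.value)
}

#' Chi-square test of independence
#'
#' Pearson statistic without continuity correction on an r x c table of
#' counts; df = (r-1)(c-1). Rows or columns whose counts are all zero are
#' dropped before testing (they carry no information and make the expected
#' counts degenerate); the test errors if fewer than 2 informative rows and
#' columns remain.
#'
#' @param counts Matrix (or table) of non-negative integer counts, at least
#'   2 x 2 after dropping all-zero margins.
#' @return List with `statistic`, `df`, `p_raw`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("degenerate table: need at least 2 non-empty rows and columns",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_raw = fit$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; input order is preserved and the
#' result is permutation-equivariant.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
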