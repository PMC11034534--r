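#' Threshold policy for the pharmacy-desert definition
#'
#' Bundles every numeric constant of the desert definition in one validated
#' object: the income criteria, the access fraction, the urbanicity radii and
#' density cut-offs, the low-vehicle override, and the significance level used
#' by the comparison tables.
#'
#' @param fpl_threshold Fraction of tract population below the Federal Poverty
#'   Level at or above which the tract meets the poverty arm of the low-income
#'   criterion (inclusive). Default 0.20.
#' @param metro_income_ratio A tract whose median household income is strictly
#'   below `metro_income_ratio` times the median income of the nearest
#'   metropolitan area meets the relative-income arm. Default 0.80.
#' @param access_fraction A tract is low-access when the fraction of its
#'   population living outside every pharmacy radius exceeds this value.
#'   Default 1/3; strictness controlled by `access_strict`.
#' @param access_strict Logical; `TRUE` (default) means strictly greater than
#'   `access_fraction` ("more than one-third"), `FALSE` means at-or-above.
#' @param radius_urban,radius_suburban,radius_rural Access radii in miles for
#'   the three urbanicity classes. Defaults 1, 5 and 10 miles.
#' @param radius_low_vehicle Radius in miles applied when a tract has fewer
#'   than `low_vehicle_count` car-owning individuals. Default 0.5 miles.
#' @param low_vehicle_count Car-owner count strictly below which the
#'   low-vehicle radius applies. Default 100.
#' @param low_vehicle_mode `"replace"` (default) uses the low-vehicle radius
#'   instead of the class radius; `"min"` uses the smaller of the two.
#' @param density_urban_min Population density (persons per square mile) at or
#'   above which a tract is urban. Default 5000.
#' @param density_rural_max Density strictly below which a tract is rural.
#'   Default 1000.
#' @param alpha Significance level for the adjusted p-values in the comparison
#'   tables. Default 0.01.
#'
#' @return An object of class `"desert_policy"`: a named list of the above.
#' @examples
#' policy <- threshold_policy()
#' policy$radius_rural
#' @export
threshold_policy <- function(fpl_threshold = 0.20,
                             metro_income_ratio = 0.80,
                             access_fraction = 1 / 3,
                             access_strict = TRUE,
                             radius_urban = 1.0,
                             radius_suburban = 5.0,
                             radius_rural = 10.0,
                             radius_low_vehicle = 0.5,
                             low_vehicle_count = 100L,
                             low_vehicle_mode = c("replace", "min"),
                             density_urban_min = 5000,
                             density_rural_max = 1000,
                             alpha = 0.01) {
  low_vehicle_mode <- match.arg(low_vehicle_mode)
  policy <- list(
    fpl_threshold = fpl_threshold,
    metro_income_ratio = metro_income_ratio,
    access_fraction = access_fraction,
    access_strict = isTRUE(access_strict),
    radius_urban = radius_urban,
    radius_suburban = radius_suburban,
    radius_rural = radius_rural,
    radius_low_vehicle = radius_low_vehicle,
    low_vehicle_count = as.integer(low_vehicle_count),
    low_vehicle_mode = low_vehicle_mode,
    density_urban_min = density_urban_min,
    density_rural_max = density_rural_max,
    alpha = alpha
  )
  class(policy) <- "desert_policy"
  validate_policy(policy)
  policy
}

validate_policy <- function(policy) {
  stopifnot(inherits(policy, "desert_policy"))
  num <- c("fpl_threshold", "metro_income_ratio", "access_fraction",
           "radius_urban", "radius_suburban", "radius_rural",
           "radius_low_vehicle", "density_urban_min", "density_rural_max",
           "alpha")
  for (f in num) {
    v <- policy[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("policy field `", f, "` must be a single finite number",
           call. = FALSE)
    }
  }
  if (policy$access_fraction <= 0 || policy$access_fraction >= 1) {
    stop("access_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(policy$radius_low_vehicle < policy$radius_urban &&
        policy$radius_urban < policy$radius_suburban &&
        policy$radius_suburban < policy$radius_rural)) {
    stop("radii must satisfy low_vehicle < urban < suburban < rural",
         call. = FALSE)
  }
  if (policy$density_rural_max >= policy$density_urban_min) {
    stop("density_rural_max must be below density_urban_min", call. = FALSE)
  }
  if (policy$alpha <= 0 || policy$alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  invisible(policy)
}

#' @export
print.desert_policy <- function(x, ...) {
  cat("<desert_policy>\n")
  cat(sprintf("  low income : >= %.0f%% below FPL  OR  median income < %.0f%% of nearest metro\n",
              100 * x$fpl_threshold, 100 * x$metro_income_ratio))
  cat(sprintf("  low access : > %.3f of population outside radius (%s)\n",
              x$access_fraction, if (x$access_strict) "strict" else "inclusive"))
  cat(sprintf("  radii (mi) : urban %.1f / suburban %.1f / rural %.1f / low-vehicle %.1f (< %d car owners, %s)\n",
              x$radius_urban, x$radius_suburban, x$radius_rural,
              x$radius_low_vehicle, x$low_vehicle_count, x$low_vehicle_mode))
  cat(sprintf("  density    : urban >= %g, rural < %g persons/sq mi\n",
              x$density_urban_min, x$density_rural_max))
  cat(sprintf("  alpha      : %g\n", x$alpha))
  invisible(x)
}

#' Read or write a threshold policy as YAML/JSON
#'
#' A policy file is a flat mapping of the [threshold_policy()] fields; absent
#' fields take their defaults, unknown fields are an error.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `read_policy()` returns a `desert_policy`; `write_policy()` returns
#'   `path` invisibly.
#' @export
read_policy <- function(path) {
  if (!file.exists(path)) stop("policy file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(threshold_policy))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown policy field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(threshold_policy, vals)
}

#' @rdname read_policy
#' @param policy A `desert_policy` object.
#' @export
write_policy <- function(policy, path) {
  validate_policy(policy)
  vals <- unclass(policy)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
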