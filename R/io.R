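# Readers and writers for the tabular and geographic formats the pipeline
# touches. Internal representation is (lat, lon) decimal degrees WGS84;
# GeoJSON geometry uses [lon, lat] axis order per the GeoJSON standard and the
# conversion happens here, never downstream.

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "geojson")))
  if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE)) "geojson" else "csv"
}

col_specs <- list(
  blocks = readr::cols(
    block_id = readr::col_character(), tract_id = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double(),
    population = readr::col_integer()),
  tracts = readr::cols(
    tract_id = readr::col_character(), state = readr::col_character(),
    land_area = readr::col_double(), population = readr::col_integer(),
    median_income = readr::col_double(), prop_below_fpl = readr::col_double(),
    car_owner_count = readr::col_integer(), .default = readr::col_double()),
  pharmacies = readr::cols(
    pharmacy_id = readr::col_character(), lat = readr::col_double(),
    lon = readr::col_double(), ownership = readr::col_character(),
    tract_id = readr::col_character(), .default = readr::col_logical()),
  metros = readr::cols(
    metro_id = readr::col_character(), lat = readr::col_double(),
    lon = readr::col_double(), median_income = readr::col_double())
)

read_table_checked <- function(path, type) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # optional columns (pharmacy tract_id, service flags) may be absent; the
  # missing-parser notice from readr is noise here
  x <- withCallingHandlers(
    readr::read_csv(path, col_types = col_specs[[type]],
                    na = c("", "NA"), progress = FALSE),
    warning = function(w) {
      if (inherits(w, "vroom_mismatched_column_name")) {
        invokeRestart("muffleWarning")
      }
    })
  missing_cols <- setdiff(required_cols[[type]], names(x))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x
}

finalize_read <- function(x, problems, type, on_invalid) {
  n_input <- nrow(x)
  if (nrow(problems) > 0) {
    msg <- paste0(nrow(problems), " invalid ", type, " record(s): ",
                  paste(utils::head(paste0(problems$id, " (", problems$problem, ")"), 5L),
                        collapse = "; "),
                  if (nrow(problems) > 5L) " ...")
    if (on_invalid == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    x <- x[!(x[[1L]] %in% problems$id), , drop = FALSE]
  }
  attr(x, "read_report") <- list(n_input = n_input, n_accepted = nrow(x),
                                 n_rejected = n_input - nrow(x),
                                 rejected = problems)
  x
}

#' Read census blocks, tracts, pharmacies, or metro areas
#'
#' CSV schemas use the documented column names (see Details); GeoJSON inputs
#' are FeatureCollections of Point features whose properties carry the
#' non-coordinate columns. Every record is validated against the type
#' invariants (coordinate ranges, non-negative counts, closed ownership
#' vocabulary, unique ids); empty strings and explicit nulls are read as
#' missing, never as zero.
#'
#' @details CSV columns: blocks `block_id, tract_id, lat, lon, population`;
#' tracts `tract_id, state, land_area, population, median_income,
#' prop_below_fpl, car_owner_count` plus optional demographic proportion
#' columns (see [demographic_cols]); pharmacies `pharmacy_id, lat, lon,
#' ownership` plus optional `tract_id` and the logical [service_flags]
#' columns (absent flag column or empty cell = unknown, not `FALSE`);
#' metros `metro_id, lat, lon, median_income`.
#'
#' @param path Input file.
#' @param format `"csv"` or `"geojson"`; default guessed from the extension.
#' @param on_invalid `"error"` (default) stops naming the offending record
#'   ids; `"drop"` keeps valid records and attaches a `read_report` attribute
#'   with input/accepted/rejected counts so nothing is silently lost.
#' @return A validated tibble; attribute `read_report` lists
#'   `n_input`, `n_accepted`, `n_rejected` and the rejected ids.
#' @export
read_blocks <- function(path, format = NULL, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  format <- guess_format(path, format)
  x <- if (format == "csv") read_table_checked(path, "blocks")
       else read_points_geojson(path, "blocks")
  x$population <- as.integer(x$population)
  finalize_read(x, check_blocks(x), "block", on_invalid)
}

#' @rdname read_blocks
#' @param blocks Optional block table; when given, tract populations are
#'   checked against the sum of member-block populations and mismatches
#'   (including tracts with population > 0 but no blocks on file) raise a
#'   warning listing the tract ids.
#' @export
read_tracts <- function(path, format = NULL, blocks = NULL,
                        on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  format <- guess_format(path, format)
  x <- if (format == "csv") read_table_checked(path, "tracts")
       else read_points_geojson(path, "tracts")
  x <- finalize_read(x, check_tracts(x), "tract", on_invalid)
  if (!is.null(blocks)) {
    bad <- check_population_consistency(x, blocks)
    if (nrow(bad) > 0) {
      warning("tract population does not equal sum of member blocks for: ",
              paste(bad$tract_id, collapse = ", "), call. = FALSE)
    }
  }
  x
}

#' @rdname read_blocks
#' @export
read_pharmacies <- function(path, format = NULL,
                            on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  format <- guess_format(path, format)
  x <- if (format == "csv") read_table_checked(path, "pharmacies")
       else read_points_geojson(path, "pharmacies")
  x$ownership <- tolower(trimws(x$ownership))
  if (!"tract_id" %in% names(x)) x$tract_id <- NA_character_
  for (f in service_flags) {           # absent flag column -> unknown
    if (!f %in% names(x)) x[[f]] <- NA
    x[[f]] <- as.logical(x[[f]])
  }
  finalize_read(x, check_pharmacies(x), "pharmacy", on_invalid)
}

#' @rdname read_blocks
#' @export
read_metros <- function(path, format = NULL, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  format <- guess_format(path, format)
  x <- if (format == "csv") read_table_checked(path, "metros")
       else read_points_geojson(path, "metros")
  finalize_read(x, check_metros(x), "metro", on_invalid)
}

#' Write an entity table as CSV or GeoJSON points
#'
#' Round-trips through [read_blocks()] and friends: write-then-read is the
#' identity on every field in both formats.
#'
#' @param x Entity tibble (blocks, tracts, pharmacies or metros).
#' @param path Output file.
#' @param type One of `"blocks"`, `"tracts"`, `"pharmacies"`, `"metros"`.
#' @param format `"csv"` or `"geojson"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_entities <- function(x, path, type = c("blocks", "tracts", "pharmacies",
                                             "metros"),
                           format = NULL) {
  type <- match.arg(type)
  format <- guess_format(path, format)
  if (format == "csv") {
    readr::write_csv(x, path, na = "")
  } else {
    write_points_geojson(x, path, type)
  }
  invisible(path)
}

# GeoJSON point helpers --------------------------------------------------------

read_points_geojson <- function(path, type) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection in ", basename(path),
         call. = FALSE)
  }
  rows <- purrr::map(g$features, function(ft) {
    coords <- ft$geometry$coordinates
    props <- purrr::map(ft$properties, function(v) if (is.null(v)) NA else v)
    c(list(lon = coords[[1]], lat = coords[[2]]), props)
  })
  x <- dplyr::bind_rows(purrr::map(rows, as_tibble))
  need <- setdiff(required_cols[[type]], names(x))
  if (length(need)) {
    stop("missing required propert(ies) in ", basename(path), ": ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x[, union(required_cols[[type]], names(x))]
}

write_points_geojson <- function(x, path, type) {
  props <- setdiff(names(x), c("lat", "lon"))
  features <- purrr::map(seq_len(nrow(x)), function(i) {
    p <- as.list(x[i, props, drop = FALSE])
    p <- purrr::map(p, function(v) if (is.na(v)) NULL else v)
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(x$lon[i], x$lat[i])),
         properties = p)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Export tract classifications as a GeoJSON choropleth layer
#'
#' One feature per classified tract with properties `tract_id`, `verdict`,
#' `urbanicity`, `prop_outside`, `low_income`, `low_access`. Geometry is the
#' tract polygon when one is supplied, otherwise a Point at the tract's
#' population-weighted block-centroid mean (classification itself never needs
#' polygons; they matter only for mapping).
#'
#' @param classifications Output of [classify_tracts()].
#' @param tracts Tract table; every classification must reference a tract.
#' @param path Output `.geojson` path.
#' @param blocks Optional block table used to place point geometries.
#' @param polygons Optional named list (by `tract_id`) of polygon rings, each
#'   a matrix/data.frame with columns `lon`, `lat`.
#' @return `path`, invisibly.
#' @export
write_classification_geojson <- function(classifications, tracts, path,
                                         blocks = NULL, polygons = NULL) {
  unknown <- setdiff(classifications$tract_id, tracts$tract_id)
  if (length(unknown)) {
    stop("classification references unknown tract_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  centers <- NULL
  if (!is.null(blocks)) centers <- tract_centers(blocks)
  features <- purrr::map(seq_len(nrow(classifications)), function(i) {
    cl <- classifications[i, ]
    geom <- NULL
    if (!is.null(polygons) && cl$tract_id %in% names(polygons)) {
      ring <- as.data.frame(polygons[[cl$tract_id]])
      coords <- purrr::map(seq_len(nrow(ring)),
                           function(j) c(ring$lon[j], ring$lat[j]))
      geom <- list(type = "Polygon", coordinates = list(coords))
    } else if (!is.null(centers) && cl$tract_id %in% centers$tract_id) {
      ctr <- centers[centers$tract_id == cl$tract_id, ]
      geom <- list(type = "Point", coordinates = c(ctr$lon, ctr$lat))
    }
    props <- list(tract_id = cl$tract_id,
                  verdict = as.character(cl$verdict),
                  urbanicity = if (is.na(cl$urbanicity)) NULL
                               else as.character(cl$urbanicity),
                  prop_outside = if (is.na(cl$prop_outside)) NULL
                                 else cl$prop_outside,
                  low_income = if (is.na(cl$low_income)) NULL else cl$low_income,
                  low_access = if (is.na(cl$low_access)) NULL else cl$low_access)
    list(type = "Feature", geometry = geom, properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
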