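#' Occurrence sets
#'
#' An `occurrence_set` is a data.frame of point records with planar
#' coordinates (km), a positional-uncertainty radius (km), a collection
#' year and a free-text source tag. The CSV exchange format has the header
#' `lon_km,lat_km,uncertainty_km,year,source`.
#'
#' @param df data.frame with columns `lon_km`, `lat_km`, `uncertainty_km`,
#'   `year` and optionally `source`.
#' @param crs_note free-text note on the coordinate system.
#' @return An `occurrence_set`.
#' @export
as_occurrence_set <- function(df, crs_note = "planar equal-area km") {
  need <- c("lon_km", "lat_km", "uncertainty_km", "year")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(df$source)) df$source <- ""
  if (any(df$uncertainty_km < 0, na.rm = TRUE))
    stop("uncertainty radii must be non-negative", call. = FALSE)
  df <- df[c(need, "source")]
  rownames(df) <- NULL
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d record(s)\n", nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read occurrence records from CSV
#'
#' One record per row. Rows whose coordinate, uncertainty or year fields do
#' not parse as numbers are skipped, and the number skipped is reported via
#' a message.
#'
#' @param path CSV file with header `lon_km,lat_km,uncertainty_km,year,source`.
#' @return An `occurrence_set`.
#' @export
load_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("lon_km", "lat_km", "uncertainty_km", "year")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(df$source)) df$source <- ""
  num <- suppressWarnings(data.frame(
    lon_km = as.numeric(df$lon_km),
    lat_km = as.numeric(df$lat_km),
    uncertainty_km = as.numeric(df$uncertainty_km),
    year = as.integer(as.numeric(df$year)),
    source = df$source
  ))
  bad <- !stats::complete.cases(num[c("lon_km", "lat_km", "uncertainty_km", "year")])
  if (any(bad))
    message(sum(bad), " malformed row(s) skipped while reading ", path)
  as_occurrence_set(num[!bad, , drop = FALSE])
}

#' @rdname load_occurrences
#' @param occ an `occurrence_set`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter records by positional uncertainty and collection year
#'
#' Records with an uncertainty radius strictly greater than
#' `max_uncertainty_km` are eliminated, as are records collected before
#' `min_year`. Boundary records (uncertainty exactly at the threshold, year
#' exactly `min_year`) are kept. Record order is preserved and the filter
#' is idempotent.
#'
#' @param occ an `occurrence_set`.
#' @param max_uncertainty_km maximum tolerated uncertainty radius (km).
#' @param min_year earliest tolerated collection year.
#' @return The filtered `occurrence_set`.
#' @export
filter_records <- function(occ, max_uncertainty_km = 13, min_year = 1940) {
  if (max_uncertainty_km <= 0 || min_year <= 0)
    stop("thresholds must be positive", call. = FALSE)
  keep <- occ$uncertainty_km <= max_uncertainty_km & occ$year >= min_year
  out <- occ[keep, , drop = FALSE]
  cell <- attr(occ, "cell")
  if (!is.null(cell)) attr(out, "cell") <- cell[keep]
  rownames(out) <- NULL
  out
}

#' Spatially thin records to one per grid cell
#'
#' Overlays a square grid of `cell_area_km2` (side `sqrt(cell_area_km2)`)
#' anchored at `origin` and keeps exactly one record per occupied cell,
#' chosen uniformly at random with the given seed, to even out record
#' density. Output order follows input order of the retained records; the
#' output size equals the number of occupied cells regardless of seed.
#'
#' @param occ an `occurrence_set`.
#' @param cell_area_km2 thinning cell area in km^2 (default 900, i.e. 30 km
#'   squares).
#' @param seed integer seed for the within-cell choice.
#' @param origin (x0, y0) anchoring the thinning grid.
#' @return The thinned `occurrence_set`.
#' @export
thin_occurrences <- function(occ, cell_area_km2 = 900, seed = 1,
                             origin = c(0, 0)) {
  if (cell_area_km2 <= 0) stop("`cell_area_km2` must be positive", call. = FALSE)
  if (!nrow(occ)) return(occ)
  side <- sqrt(cell_area_km2)
  key <- paste(floor((occ$lon_km - origin[1L]) / side),
               floor((occ$lat_km - origin[2L]) / side))
  set.seed(seed)
  keep_idx <- unlist(lapply(split(seq_len(nrow(occ)), key), function(i)
    if (length(i) == 1L) i else sample(i, 1L)), use.names = FALSE)
  keep_idx <- sort(keep_idx)
  out <- occ[keep_idx, , drop = FALSE]
  cell <- attr(occ, "cell")
  if (!is.null(cell)) attr(out, "cell") <- cell[keep_idx]
  rownames(out) <- NULL
  out
}

#' Map records to presence cells of a stack
#'
#' Each record is assigned to the grid cell containing it (half-open cells,
#' floor convention; see [point_to_cell()]); records outside the stack
#' extent are dropped with a message, and duplicate cells are deduplicated.
#'
#' @param occ an `occurrence_set`.
#' @param stack an `env_stack` (or `raster_layer`).
#' @return Sorted integer vector of unique presence cell indices.
#' @export
grid_presence <- function(occ, stack) {
  cells <- point_to_cell(occ$lon_km, occ$lat_km, stack)
  if (anyNA(cells)) {
    message(sum(is.na(cells)), " record(s) outside the stack extent dropped")
    cells <- cells[!is.na(cells)]
  }
  sort(unique(cells))
}
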