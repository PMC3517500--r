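#' Sampling-effort weighting surface (bias grid)
#'
#' The weighting surface at each cell centre is the Gaussian-kernel density
#' of presence records, `d(c) = sum_records exp(-dist^2 / (2 sd^2))` with a
#' kernel standard deviation of 200 km by default, linearly rescaled so the
#' maximum weight is 20 and the minimum is 1 (avoiding extreme
#' down-weighting of heavily collected cells). High weights mark heavily
#' sampled neighbourhoods; model fitting divides presence weights by the
#' bias to counteract uneven collection effort.
#'
#' @param occ a non-empty `occurrence_set`.
#' @param template a `raster_layer` defining the grid.
#' @param kernel_sd_km Gaussian kernel standard deviation (km).
#' @param w_min,w_max weight range after rescaling.
#' @return An object of class `bias_grid` with elements `weights` (a
#'   `raster_layer`), `kernel_sd_km`, `w_min`, `w_max`.
#' @export
build_bias_grid <- function(occ, template, kernel_sd_km = 200,
                            w_min = 1, w_max = 20) {
  if (!nrow(occ))
    stop("degenerate input: the occurrence set is empty", call. = FALSE)
  stopifnot(inherits(template, "raster_layer"))
  ctr <- cell_centers(template)
  # kernel sums accumulated record-by-record: O(cells x records) overall,
  # but only one cells-length vector live at a time
  d <- numeric(nrow(ctr))
  inv2s2 <- 1 / (2 * kernel_sd_km^2)
  for (i in seq_len(nrow(occ))) {
    d2 <- (ctr$x - occ$lon_km[i])^2 + (ctr$y - occ$lat_km[i])^2
    d <- d + exp(-d2 * inv2s2)
  }
  rng <- range(d)
  w <- if (rng[2L] > rng[1L])
    w_min + (w_max - w_min) * (d - rng[1L]) / (rng[2L] - rng[1L])
  else rep(w_min, length(d))
  wl <- raster_layer(matrix(w, nrow(template$values), ncol(template$values)),
                     cell_km = template$cell_km, origin = template$origin,
                     name = "bias_weight")
  structure(list(weights = wl, kernel_sd_km = kernel_sd_km,
                 w_min = w_min, w_max = w_max),
            class = "bias_grid")
}

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("<bias_grid> kernel sd %g km, weights in [%g, %g]\n",
              x$kernel_sd_km, min(x$weights$values), max(x$weights$values)))
  invisible(x)
}

#' Per-presence weights from a bias grid
#'
#' Presence records from heavily sampled neighbourhoods are down-weighted
#' in proportion to the inverse bias weight at their cell; the weights are
#' normalized to sum to the number of presences.
#'
#' @param cells presence cell indices.
#' @param bias a `bias_grid` (or `NULL` for unit weights).
#' @return Numeric weight per presence, summing to `length(cells)`.
#' @export
presence_bias_weights <- function(cells, bias = NULL) {
  m <- length(cells)
  if (is.null(bias)) return(rep(1, m))
  w <- 1 / as.vector(bias$weights$values)[cells]
  w * (m / sum(w))
}
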