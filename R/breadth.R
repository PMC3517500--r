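#' Levin's standardized niche breadth from a suitability grid
#'
#' Normalizes the suitability scores over the region to proportions
#' `p_i = s_i / sum(s)`, computes Levin's measure `B = 1 / sum(p_i^2)` and
#' returns the standardized value `B_A = (B - 1) / (n - 1)` where n is the
#' number of region cells. `B_A` is 0 when exactly one cell has nonzero
#' suitability (maximal concentration) and 1 when all cells are equally
#' suitable, and is invariant to rescaling the suitability surface.
#'
#' @param suit a `suitability_grid` or `raster_layer`.
#' @param region_mask optional `raster_layer`; breadth is computed over
#'   cells where the mask is > 0 (default: all non-nodata cells).
#' @return Standardized breadth in \[0, 1\].
#' @export
levins_breadth <- function(suit, region_mask = NULL) {
  s <- as.vector(suit$values)
  use <- !is.na(s)
  if (!is.null(region_mask)) {
    m <- as.vector(region_mask$values)
    use <- use & !is.na(m) & m > 0
  }
  s <- s[use]
  n <- length(s)
  if (n < 2) stop("degenerate input: breadth needs at least two region cells",
                  call. = FALSE)
  if (all(s == 0)) stop("degenerate input: suitability is zero everywhere",
                        call. = FALSE)
  p <- s / sum(s)
  B <- 1 / sum(p^2)
  (B - 1) / (n - 1)
}

#' Null distribution of niche breadth from random presences
#'
#' For each replicate, `n_points` cells are sampled uniformly without
#' replacement within the species' range mask, a full-variable model is
#' fitted to them exactly as for the real species (same background, same
#' features, same link, same breadth region), and the standardized breadth
#' of its suitability surface is recorded. The resulting values form the
#' null expectation of breadth given the environments available inside the
#' range; no sampling-bias grid is applied to the random replicates.
#'
#' @param range_mask `raster_layer` mask of the species range (> 0 inside).
#' @param stack the `env_stack`.
#' @param n_points presences per replicate (customarily the species'
#'   thinned presence count); must not exceed the mask cell count.
#' @param features a `feature_set`.
#' @param n_rep number of replicates (default 100).
#' @param seed integer RNG seed.
#' @param background_cells background cell indices (default: all jointly
#'   non-nodata cells).
#' @param region_mask breadth region (default: the whole modelling extent).
#' @param link suitability link for breadth (default logistic, the same
#'   surface as mapped).
#' @param ... passed to [fit_maxent()].
#' @return Numeric vector of `n_rep` standardized breadth values.
#' @export
null_breadth_distribution <- function(range_mask, stack, n_points, features,
                                      n_rep = 100, seed = 1,
                                      background_cells = NULL,
                                      region_mask = NULL,
                                      link = "logistic", ...) {
  mask_cells <- which(!is.na(as.vector(range_mask$values)) &
                        as.vector(range_mask$values) > 0)
  if (n_points > length(mask_cells))
    stop("`n_points` exceeds the number of range cells", call. = FALSE)
  if (is.null(background_cells)) background_cells <- complete_cells(stack)
  bg_fm <- feature_matrix(features, stack, background_cells)
  set.seed(seed)
  vapply(seq_len(n_rep), function(r) {
    cells <- sample(mask_cells, n_points)
    mod <- fit_maxent(cells, background_cells, features, stack,
                      bg_fm = bg_fm, ...)
    suit <- predict_suitability(mod, stack, link = link)
    levins_breadth(suit, region_mask)
  }, numeric(1))
}

#' Bundle actual and null breadth values
#'
#' @param b_actual standardized breadth of the real species model.
#' @param null_values vector of null breadths
#'   ([null_breadth_distribution()]).
#' @param species species tag.
#' @param n_cells number of region cells used.
#' @return An object of class `breadth_result`; the element `differences`
#'   holds `b_actual - null_values` (negative values: narrower than the
#'   null expectation).
#' @export
breadth_result <- function(b_actual, null_values, species = "", n_cells = NA) {
  if (!length(null_values)) stop("`null_values` must be non-empty", call. = FALSE)
  structure(list(species = species, b_actual = b_actual,
                 null_values = null_values,
                 differences = b_actual - null_values,
                 n_cells = n_cells),
            class = "breadth_result")
}

#' @export
print.breadth_result <- function(x, ...) {
  cat(sprintf(paste0("<breadth_result> %s: B_A = %.4f, null mean = %.4f ",
                     "(%d replicates), mean difference = %+.4f\n"),
              x$species, x$b_actual, mean(x$null_values),
              length(x$null_values), mean(x$differences)))
  invisible(x)
}

#' Compare background-adjusted niche breadth between two species
#'
#' Pooled two-sample t-test on the two collections of differences
#' (actual minus null breadth), with `df = n_A + n_B - 2`. The verdict is
#' `"A narrower"` / `"B narrower"` when the mean differences are
#' distinguishable at the 5\% level, otherwise `"indistinguishable"`. If
#' the pooled variance is zero the t statistic is undefined and the
#' verdict falls back to the sign of the means.
#'
#' @param result_A,result_B `breadth_result` objects.
#' @return An object of class `breadth_comparison` with the per-species
#'   mean differences, `t`, `df`, `p` and `verdict`.
#' @export
breadth_difference_test <- function(result_A, result_B) {
  dA <- result_A$differences; dB <- result_B$differences
  tagA <- if (nzchar(result_A$species)) result_A$species else "A"
  tagB <- if (nzchar(result_B$species)) result_B$species else "B"
  nA <- length(dA); nB <- length(dB)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * stats::var(dA) + (nB - 1) * stats::var(dB)) / df
  if (is.na(sp2) || sp2 <= 0) {
    t <- NA_real_; p <- NA_real_
  } else {
    t <- (mean(dA) - mean(dB)) / sqrt(sp2 * (1 / nA + 1 / nB))
    p <- 2 * stats::pt(-abs(t), df)
  }
  verdict <- if ((is.na(p) && mean(dA) != mean(dB)) ||
                 (!is.na(p) && p < 0.05)) {
    if (mean(dA) < mean(dB)) sprintf("%s narrower", tagA)
    else sprintf("%s narrower", tagB)
  } else "indistinguishable"
  structure(list(mean_A = mean(dA), mean_B = mean(dB),
                 species_A = tagA, species_B = tagB,
                 t = t, df = df, p = p, verdict = verdict),
            class = "breadth_comparison")
}

#' @export
print.breadth_comparison <- function(x, ...) {
  cat(sprintf(paste0("<breadth_comparison> %s: %+.4f vs %s: %+.4f, ",
                     "t_%d = %.3f, p = %.3g -> %s\n"),
              x$species_A, x$mean_A, x$species_B, x$mean_B,
              x$df, x$t, x$p, x$verdict))
  invisible(x)
}

#' Serialize breadth results as JSON
#' @param x a `breadth_result` or `breadth_comparison`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_breadth_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
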