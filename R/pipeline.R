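#' Select background cells for model fitting
#'
#' Uses every jointly non-nodata cell when there are at most `max_cells`,
#' otherwise a seeded uniform sample of `max_cells` of them (the customary
#' 10,000-cell background default).
#'
#' @param stack an `env_stack`.
#' @param max_cells background size cap (default 10000).
#' @param seed integer seed used only when sampling is needed.
#' @return Integer vector of background cell indices.
#' @export
select_background <- function(stack, max_cells = 10000, seed = 1) {
  cells <- complete_cells(stack)
  if (length(cells) <= max_cells) return(cells)
  set.seed(seed)
  sort(sample(cells, max_cells))
}

#' Fit a distribution model from occurrence records
#'
#' Convenience wrapper chaining the standard steps: grid the records to
#' presence cells, optionally derive per-record weights from a
#' sampling-bias grid (`bias_mode = "presence"` down-weights records from
#' heavily sampled neighbourhoods, the literal reading of the weighting
#' surface; `"background"` instead carries the effort correction on the
#' background cells, the classic bias-file convention), select the
#' background, and fit the penalized maximum-entropy model.
#'
#' @param occ an `occurrence_set` (already filtered/thinned as desired).
#' @param stack an `env_stack`.
#' @param features a `feature_set` (default: linear + quadratic + hinge +
#'   categorical over all layers).
#' @param bias optional `bias_grid`.
#' @param bias_mode `"presence"` (default) or `"background"`.
#' @param background_cells optional explicit background (default
#'   [select_background()]).
#' @param seed seed for background sampling.
#' @param ... passed to [fit_maxent()].
#' @return A `maxent_model`; the presence cells used are stored in
#'   attribute `presence_cells`.
#' @export
fit_sdm <- function(occ, stack, features = NULL, bias = NULL,
                    bias_mode = c("presence", "background"),
                    background_cells = NULL, seed = 1, ...) {
  bias_mode <- match.arg(bias_mode)
  pres <- point_to_cell(occ$lon_km, occ$lat_km, stack)
  pres <- pres[!is.na(pres)]
  if (is.null(background_cells))
    background_cells <- select_background(stack, seed = seed)
  if (is.null(features))
    features <- make_features(stack,
                              classes = c("linear", "quadratic", "hinge",
                                          "categorical"),
                              background_cells = background_cells)
  pw <- NULL; bgw <- NULL
  if (!is.null(bias)) {
    if (bias_mode == "presence") pw <- presence_bias_weights(pres, bias)
    else bgw <- as.vector(bias$weights$values)[background_cells]
  }
  mod <- fit_maxent(pres, background_cells, features, stack,
                    presence_weights = pw, bg_weights = bgw, ...)
  attr(mod, "presence_cells") <- pres
  mod
}
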