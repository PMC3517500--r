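#' Generate a synthetic environmental landscape
#'
#' Continuous layers are spatially autocorrelated fields built by smoothing
#' white noise with a separable Gaussian kernel (standard deviation
#' `smoothness_km`) and rescaling to \[0, 1\]. Categorical layers are
#' obtained by cutting an independent smoothed field into `n_classes`
#' equal-frequency bins coded `1..n_classes`, emulating an ecoregion map.
#' The same seed reproduces the stack bit-for-bit.
#'
#' @param rows,cols grid dimensions (>= 16 each).
#' @param n_continuous number of continuous layers (>= 1), named `env1..`.
#' @param n_categorical number of categorical layers, named `cat1..`.
#' @param smoothness_km kernel standard deviation in km (>= `cell_km`).
#' @param cell_km cell side length in km.
#' @param n_classes number of categorical codes per categorical layer.
#' @param seed integer RNG seed.
#' @return An `env_stack`.
#' @export
generate_landscape <- function(rows, cols, n_continuous = 3, n_categorical = 1,
                               smoothness_km = 150, cell_km = 15,
                               n_classes = 5, seed = 1) {
  if (rows < 16 || cols < 16)
    stop("`rows` and `cols` must each be at least 16", call. = FALSE)
  if (n_continuous < 1)
    stop("at least one continuous layer is required", call. = FALSE)
  if (n_categorical < 0)
    stop("`n_categorical` must be non-negative", call. = FALSE)
  if (smoothness_km < cell_km)
    stop("`smoothness_km` must be at least the cell size", call. = FALSE)
  set.seed(seed)
  sd_cells <- smoothness_km / cell_km
  layers <- vector("list", n_continuous + n_categorical)
  for (i in seq_len(n_continuous)) {
    f <- smooth_field(matrix(stats::rnorm(rows * cols), rows, cols), sd_cells)
    f <- (f - min(f)) / (max(f) - min(f))
    layers[[i]] <- raster_layer(f, cell_km = cell_km, name = paste0("env", i))
  }
  for (j in seq_len(n_categorical)) {
    f <- smooth_field(matrix(stats::rnorm(rows * cols), rows, cols), sd_cells)
    codes <- matrix(as.numeric(cut(f, breaks = stats::quantile(
      f, probs = seq(0, 1, length.out = n_classes + 1)),
      include.lowest = TRUE, labels = FALSE)), rows, cols)
    layers[[n_continuous + j]] <- raster_layer(
      codes, cell_km = cell_km, name = paste0("cat", j), kind = "categorical")
  }
  env_stack(layers)
}

# Separable Gaussian smoothing with edge renormalization so border cells
# average only over cells inside the grid.
smooth_field <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  band <- function(n) {
    idx <- seq_len(n)
    k <- outer(idx, idx, function(i, j) stats::dnorm(i - j, sd = sd_cells))
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Response-curve specifications for virtual species
#'
#' A virtual species responds to each named environmental variable with
#' either a Gaussian performance curve `A * exp(-(x - mu)^2 / (2 sigma^2))`
#' or a constant level; variables without a response do not constrain the
#' species.
#'
#' @param amplitude peak height `A` in (0, 1\].
#' @param optimum position `mu` of the peak on the variable's scale.
#' @param width Gaussian standard deviation `sigma` (> 0).
#' @return A response specification list.
#' @export
response_gaussian <- function(amplitude, optimum, width) {
  if (amplitude <= 0 || amplitude > 1) stop("`amplitude` must be in (0, 1]", call. = FALSE)
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  list(type = "gaussian", amplitude = amplitude, optimum = optimum, width = width)
}

#' @rdname response_gaussian
#' @param level constant suitability in \[0, 1\].
#' @export
response_constant <- function(level) {
  if (level < 0 || level > 1) stop("`level` must be in [0, 1]", call. = FALSE)
  list(type = "constant", level = level)
}

#' Define a virtual species
#'
#' @param responses named list of response specifications
#'   ([response_gaussian()] / [response_constant()]), names matching
#'   environmental layer names. At least one response must be non-constant.
#' @param aggregation how per-variable responses combine into suitability:
#'   `"geometric_mean"` (default; robust to adding near-constant responses)
#'   or `"product"`.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(responses,
                            aggregation = c("geometric_mean", "product")) {
  aggregation <- match.arg(aggregation)
  if (!length(responses) || is.null(names(responses)) ||
      any(!nzchar(names(responses))))
    stop("`responses` must be a non-empty named list", call. = FALSE)
  types <- vapply(responses, `[[`, character(1), "type")
  if (!any(types != "constant"))
    stop("at least one response must be non-constant", call. = FALSE)
  structure(list(responses = responses, aggregation = aggregation),
            class = "virtual_species")
}

eval_response <- function(resp, x) {
  switch(resp$type,
         gaussian = resp$amplitude *
           exp(-(x - resp$optimum)^2 / (2 * resp$width^2)),
         constant = rep(resp$level, length(x)),
         stop("unknown response type ", resp$type, call. = FALSE))
}

#' True suitability of a virtual species over a landscape
#'
#' Evaluates every response on its layer and aggregates cellwise (product
#' or geometric mean over the species' responses). The result is the
#' ground-truth suitability surface used to sample presences and to score
#' parameter recovery.
#'
#' @param species a `virtual_species`.
#' @param stack an `env_stack` containing every response variable.
#' @return A continuous `raster_layer` with values in \[0, 1\].
#' @export
true_suitability <- function(species, stack) {
  stopifnot(inherits(species, "virtual_species"))
  missing <- setdiff(names(species$responses), layer_names(stack))
  if (length(missing))
    stop("response variable(s) not in stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ref <- stack[[1L]]
  acc <- NULL
  for (v in names(species$responses)) {
    r <- eval_response(species$responses[[v]], as.vector(stack[[v]]$values))
    acc <- if (is.null(acc)) log(pmax(r, 0)) else acc + log(pmax(r, 0))
  }
  if (species$aggregation == "geometric_mean")
    acc <- acc / length(species$responses)
  s <- exp(acc)
  s[is.nan(s)] <- 0
  raster_layer(matrix(s, nrow(ref$values), ncol(ref$values)),
               cell_km = ref$cell_km, origin = ref$origin,
               name = "suitability")
}

#' Build a specialist/generalist scenario under a conceptual niche model
#'
#' Under the *standard* model the two species exploit the focal resource
#' with equal total area under the response curve (`A * sigma` equal within
#' 1\%) but the specialist peaks higher over a narrower range. Under the
#' *alternative* model the peaks are equal and the specialist's area is
#' smaller. The generalist responds (non-constantly) to more variables than
#' the specialist. Optima are jittered by the seed within the central part
#' of the \[0, 1\] gradient so scenarios differ across seeds while the
#' invariants hold exactly.
#'
#' @param model_type `"standard"` or `"alternative"`.
#' @param focal_variable name of the focal gradient (a continuous layer).
#' @param seed integer seed for the optimum jitter.
#' @param other_variables names of the two secondary gradients (the
#'   specialist uses the first, the generalist both).
#' @return An object of class `scenario_spec` with elements `model_type`,
#'   `specialist`, `generalist`, `focal_variable`, and `range_thresholds`,
#'   the per-role [species_range_mask()] thresholds (generous for the
#'   specialist, whose mapped range includes much marginal habitat;
#'   conservative core for the generalist, whose records spill beyond the
#'   mapped range — the way published range maps treat wide-ranging
#'   carnivores).
#' @export
make_scenario <- function(model_type = c("standard", "alternative"),
                          focal_variable = "env1", seed = 1,
                          other_variables = c("env2", "env3")) {
  model_type <- match.arg(model_type)
  if (length(other_variables) < 2)
    stop("two secondary variables are required", call. = FALSE)
  set.seed(seed)
  mu_f <- stats::runif(1, 0.40, 0.60)
  mu_o <- stats::runif(2, 0.35, 0.65)
  if (model_type == "standard") {
    A_s <- 0.90; s_s <- 0.10            # area A*sigma = 0.090
    A_g <- 0.45; s_g <- 0.20            # equal area, half the peak
  } else {
    A_s <- 0.85; s_s <- 0.08            # equal peaks, smaller area
    A_g <- 0.85; s_g <- 0.30
  }
  sp_resp <- stats::setNames(list(
    response_gaussian(A_s, mu_f, s_s),
    response_gaussian(0.9, mu_o[1L], 0.15)
  ), c(focal_variable, other_variables[1L]))
  gen_resp <- stats::setNames(list(
    response_gaussian(A_g, mu_f, s_g),
    response_gaussian(0.9, mu_o[1L], 0.35),
    response_gaussian(0.9, mu_o[2L], 0.35)
  ), c(focal_variable, other_variables[1:2]))
  out <- structure(list(model_type = model_type,
                        specialist = virtual_species(sp_resp),
                        generalist = virtual_species(gen_resp),
                        focal_variable = focal_variable,
                        range_thresholds = c(specialist = 0.05,
                                             generalist = 0.70)),
                   class = "scenario_spec")
  validate_scenario(out)
  out
}

validate_scenario <- function(sc) {
  rs <- sc$specialist$responses[[sc$focal_variable]]
  rg <- sc$generalist$responses[[sc$focal_variable]]
  area_s <- rs$amplitude * rs$width
  area_g <- rg$amplitude * rg$width
  if (sc$model_type == "standard") {
    if (abs(area_s - area_g) / area_g > 0.01 || rs$amplitude <= rg$amplitude)
      stop("standard scenario must have equal focal areas and a higher specialist peak",
           call. = FALSE)
  } else {
    if (abs(rs$amplitude - rg$amplitude) > 0.01 * rg$amplitude ||
        area_s >= area_g)
      stop("alternative scenario must have equal focal peaks and a smaller specialist area",
           call. = FALSE)
  }
  invisible(sc)
}

#' Sample biased, noisy presence records from a suitability surface
#'
#' Cells are drawn with replacement with probability proportional to
#' suitability times the sampling-bias field (bias = 1 everywhere if
#' absent), emulating collection effort concentrated near well-sampled
#' areas. Coordinates are the source cell centre plus a uniform jitter in
#' `[-jitter_km, jitter_km]` on each axis; positional-uncertainty radii and
#' collection years are drawn uniformly within the stated ranges so the
#' downstream record filters are exercised.
#'
#' @param suitability a `raster_layer` with values in \[0, 1\].
#' @param n number of records (>= 1).
#' @param bias_field optional `raster_layer` of relative sampling effort.
#' @param jitter_km half-width of the coordinate jitter (default half a cell).
#' @param uncertainty_range_km (lo, hi) for uniform uncertainty radii.
#' @param year_range (lo, hi) for uniform integer collection years.
#' @param seed integer RNG seed.
#' @return An `occurrence_set` (data.frame with columns `lon_km`, `lat_km`,
#'   `uncertainty_km`, `year`, `source`) with attribute `cell` giving each
#'   record's source cell index.
#' @export
sample_presences <- function(suitability, n, bias_field = NULL,
                             jitter_km = suitability$cell_km / 2,
                             uncertainty_range_km = c(0, 25),
                             year_range = c(1900, 2000), seed = 1) {
  stopifnot(inherits(suitability, "raster_layer"))
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  s <- as.vector(suitability$values)
  w <- ifelse(is.na(s), 0, s)
  if (!is.null(bias_field)) {
    b <- as.vector(bias_field$values)
    w <- w * ifelse(is.na(b), 0, b)
  }
  if (all(w <= 0))
    stop("degenerate input: suitability (x bias) is zero everywhere", call. = FALSE)
  set.seed(seed)
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  ctr <- cell_centers(suitability)
  occ <- data.frame(
    lon_km = ctr$x[cells] + stats::runif(n, -jitter_km, jitter_km),
    lat_km = ctr$y[cells] + stats::runif(n, -jitter_km, jitter_km),
    uncertainty_km = stats::runif(n, uncertainty_range_km[1L],
                                  uncertainty_range_km[2L]),
    year = sample(seq(year_range[1L], year_range[2L]), n, replace = TRUE),
    source = "synthetic"
  )
  occ <- as_occurrence_set(occ)
  attr(occ, "cell") <- cells
  occ
}

#' Derive a species range mask from true suitability
#'
#' Emulates an expert range map: cells whose true suitability is at least
#' `threshold_prop` of the maximum belong to the range. The default 0.25
#' covers most occupied habitat (about the 1.7-sigma envelope of a Gaussian
#' response) while excluding clearly unsuitable terrain, the way published
#' range polygons include marginal but not unoccupied habitat.
#'
#' @param suitability a `raster_layer`.
#' @param threshold_prop proportion of the maximum suitability (0-1).
#' @return A `raster_layer` mask (1 inside the range, 0 outside).
#' @export
species_range_mask <- function(suitability, threshold_prop = 0.25) {
  v <- suitability$values
  thr <- threshold_prop * max(v, na.rm = TRUE)
  m <- ifelse(is.na(v), NA, as.numeric(v >= thr))
  raster_layer(m, cell_km = suitability$cell_km, origin = suitability$origin,
               name = "range_mask")
}
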