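#' Default L1 regularization for a feature
#'
#' Follows the customary maximum-entropy SDM defaults: a feature-class
#' base value interpolated against the presence sample size m
#' (linear/quadratic/product: 1.0 at m <= 10 falling to 0.5 at m >= 100;
#' categorical: 0.65 falling to 0.25 at m >= 30; hinge: 0.5 throughout),
#' multiplied by the feature's standard deviation over the presence sites
#' (floored at 0.05 on the \[0, 1\] feature scale) divided by sqrt(m).
#'
#' @param class feature class string.
#' @param m presence count.
#' @param sd_presence feature standard deviation over presences.
#' @param multiplier global regularization multiplier.
#' @return Scalar beta for the feature.
#' @export
default_beta <- function(class, m, sd_presence, multiplier = 1) {
  base <- switch(class,
    linear = , quadratic = , product =
      stats::approx(c(0, 10, 30, 100), c(1, 1, 0.6, 0.5), m, rule = 2)$y,
    hinge = 0.5,
    categorical =
      stats::approx(c(0, 10, 17, 30), c(0.65, 0.65, 0.5, 0.25), m, rule = 2)$y,
    stop("unknown feature class ", class, call. = FALSE))
  multiplier * base * max(sd_presence, 0.05) / sqrt(m)
}

#' Fit a presence-background maximum-entropy model
#'
#' Finds the Gibbs distribution `q_lambda(i) = bgw_i exp(lambda . f_i) / Z`
#' over the background cells that maximizes the weighted, L1-penalized
#' log-likelihood of the presences,
#' `L(lambda) = (1/m) sum_i w_i log q(x_i) - sum_j beta_j |lambda_j|`,
#' with presence weights normalized to sum to the presence count m
#' (weights proportional to the inverse sampling-bias weight down-weight
#' records from heavily collected neighbourhoods). Optimization is
#' coordinate-wise proximal ascent with soft-thresholding and
#' step-halving, so the penalized objective is non-decreasing; convergence
#' is declared when the largest L1 subgradient falls below `tol`.
#' Presence cells are ordinarily also members of the background (the
#' standard presence-background construction).
#'
#' @param presence_cells integer cell indices of the presences (repeats
#'   allowed: several records may share a cell); at least 5.
#' @param background_cells integer cell indices of the background.
#' @param features a `feature_set`.
#' @param stack the `env_stack` the cells index into.
#' @param presence_weights positive per-record weights (default unit); see
#'   [presence_bias_weights()].
#' @param bg_weights optional positive background cell weights (the
#'   `bias_mode = "background"` alternative, where the background rather
#'   than the presences carries the effort correction).
#' @param beta_multiplier global regularization multiplier.
#' @param beta optional explicit per-feature beta vector (overrides the
#'   defaults; recycled if scalar).
#' @param max_iter,tol optimizer controls.
#' @param lambda_cap safeguard bound on |lambda_j| (a warning is issued if
#'   it binds, which indicates an effectively unbounded optimum).
#' @param bg_fm optional precomputed background feature matrix
#'   (`feature_matrix(features, stack, background_cells)`), to avoid
#'   recomputation across repeated fits on the same background.
#' @return An object of class `maxent_model`.
#' @export
fit_maxent <- function(presence_cells, background_cells, features, stack,
                       presence_weights = NULL, bg_weights = NULL,
                       beta_multiplier = 1, beta = NULL,
                       max_iter = 500, tol = 1e-6, lambda_cap = 100,
                       bg_fm = NULL) {
  m <- length(presence_cells)
  if (m < 5) stop("at least 5 presence records are required", call. = FALSE)
  if (!length(features)) stop("the feature set is empty", call. = FALSE)
  if (is.null(bg_fm)) bg_fm <- feature_matrix(features, stack, background_cells)
  if (anyNA(bg_fm))
    stop("background cells must have complete data for all features", call. = FALSE)
  pos <- match(presence_cells, background_cells)
  pres_fm <- if (anyNA(pos)) feature_matrix(features, stack, presence_cells)
             else bg_fm[pos, , drop = FALSE]
  if (anyNA(pres_fm))
    stop("presence cells must have complete data for all features", call. = FALSE)

  w <- if (is.null(presence_weights)) rep(1, m) else presence_weights
  if (length(w) != m || any(w <= 0))
    stop("`presence_weights` must be positive, one per presence", call. = FALSE)
  w <- w * (m / sum(w))
  pbar <- as.vector(crossprod(pres_fm, w)) / m

  if (is.null(beta)) {
    sds <- apply(pres_fm, 2L, stats::sd)
    cls <- vapply(unclass(features), `[[`, character(1), "class")
    beta <- vapply(seq_along(cls), function(j)
      default_beta(cls[j], m, sds[j], beta_multiplier), numeric(1))
  } else beta <- rep_len(beta, ncol(bg_fm))

  bgw <- if (is.null(bg_weights)) rep(1, length(background_cells))
         else bg_weights
  fit <- maxent_core(bg_fm, pbar, beta, bgw, as.integer(max_iter), tol,
                     lambda_cap)
  if (fit$capped)
    warning("some coefficients hit the safeguard cap; the optimum may be unbounded",
            call. = FALSE)
  if (!fit$converged)
    message("maxent fit stopped at max_iter = ", max_iter,
            " before reaching tol = ", tol)

  structure(list(features = features, lambda = as.vector(fit$lambda),
                 beta = beta, H = fit$H, logZ = fit$logZ,
                 q = as.vector(fit$q),
                 background_cells = background_cells, bg_weights = bgw,
                 presence_count = m, pbar = pbar,
                 converged = fit$converged, iterations = fit$iterations,
                 objective = as.vector(fit$objective)),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d feature(s), %d non-zero coefficient(s), ",
                     "%d background cell(s)\n  entropy H = %.4f, gain = %.4f, %s\n"),
              length(x$lambda), sum(x$lambda != 0), length(x$background_cells),
              x$H, maxent_gain(x),
              if (x$converged) sprintf("converged in %d sweep(s)", x$iterations)
              else "not converged"))
  invisible(x)
}

#' Regularized training gain of a fitted model
#'
#' The penalized mean presence log-likelihood relative to a uniform
#' background model: `G = lambda . pbar - log Z + log N_background -
#' sum_j beta_j |lambda_j|`. A null (all-zero) model has gain 0.
#'
#' @param model a `maxent_model`.
#' @return Scalar gain (nats).
#' @export
maxent_gain <- function(model) {
  sum(model$lambda * model$pbar) - model$logZ +
    log(length(model$background_cells)) -
    sum(model$beta * abs(model$lambda))
}

# Raw (Gibbs) density for arbitrary feature rows, normalized by the
# model's background partition function.
predict_raw_fm <- function(model, fm) {
  exp(as.vector(fm %*% model$lambda) - model$logZ)
}

#' Predict habitat suitability over a stack
#'
#' `raw` is the Gibbs density normalized over the training background (it
#' sums to 1 there when background weights are uniform); `logistic` is the
#' classic suitability transform `s = e^H r / (1 + e^H r)` using the
#' fitted distribution's entropy H, giving values in \[0, 1\] with 0.5 at
#' "typical" background sites. Cells with nodata in any needed variable
#' predict `NA`; unseen categorical codes contribute feature value 0.
#'
#' @param model a `maxent_model`.
#' @param stack an `env_stack` congruent with the training features.
#' @param link `"logistic"` (default) or `"raw"`.
#' @return A `suitability_grid`: a `raster_layer` with attribute `link`.
#' @export
predict_suitability <- function(model, stack, link = c("logistic", "raw")) {
  link <- match.arg(link)
  fm <- feature_matrix(model$features, stack)
  r <- predict_raw_fm(model, fm)
  s <- if (link == "logistic") {
    eh <- exp(model$H) * r
    pmin(1, pmax(0, eh / (1 + eh)))
  } else r
  ref <- stack[[1L]]
  out <- raster_layer(matrix(s, nrow(ref$values), ncol(ref$values)),
                      cell_km = ref$cell_km, origin = ref$origin,
                      name = "suitability")
  attr(out, "link") <- link
  class(out) <- c("suitability_grid", class(out))
  out
}

#' Presence-background AUC
#'
#' The probability that a randomly selected presence point scores higher
#' than a randomly selected background location (Mann-Whitney pair
#' statistic), with ties counted one half.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_presence_background <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' k-fold cross-validation of a maximum-entropy model
#'
#' Presences are partitioned into k seeded folds; each fold is held out
#' once, a model is fitted on the remainder, and the test AUC contrasts
#' the held-out presences against the full background. The k per-fold
#' models are retained so downstream response curves can use "the average
#' of the k models".
#'
#' @param presence_cells presence cell indices (length >= k).
#' @param background_cells background cell indices.
#' @param features a `feature_set`.
#' @param stack the `env_stack`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the partition.
#' @param presence_weights optional per-record weights.
#' @param ... further arguments passed to [fit_maxent()].
#' @return An object of class `maxent_cv` with elements `models`, `folds`,
#'   `auc` (per fold) and `mean_auc`.
#' @export
crossvalidate <- function(presence_cells, background_cells, features, stack,
                          k = 10, seed = 1, presence_weights = NULL, ...) {
  m <- length(presence_cells)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (k > m) stop("`k` may not exceed the presence count", call. = FALSE)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), m))
  bg_fm <- feature_matrix(features, stack, background_cells)
  models <- vector("list", k)
  aucs <- numeric(k)
  for (fold in seq_len(k)) {
    train <- folds != fold
    wtr <- if (is.null(presence_weights)) NULL else presence_weights[train]
    models[[fold]] <- fit_maxent(presence_cells[train], background_cells,
                                 features, stack, presence_weights = wtr,
                                 bg_fm = bg_fm, ...)
    test_pos <- match(presence_cells[!train], background_cells)
    test_fm <- if (anyNA(test_pos))
      feature_matrix(features, stack, presence_cells[!train])
    else bg_fm[test_pos, , drop = FALSE]
    ps <- predict_raw_fm(models[[fold]], test_fm)
    bs <- predict_raw_fm(models[[fold]], bg_fm)
    aucs[fold] <- auc_presence_background(ps, bs)
  }
  structure(list(models = models, folds = folds, auc = aucs,
                 mean_auc = mean(aucs), k = k, seed = seed),
            class = "maxent_cv")
}

#' @export
print.maxent_cv <- function(x, ...) {
  cat(sprintf("<maxent_cv> %d fold(s), mean test AUC = %.3f (range %.3f-%.3f)\n",
              x$k, x$mean_auc, min(x$auc), max(x$auc)))
  invisible(x)
}

#' Mean cross-validated suitability surface
#'
#' Cellwise mean of the per-fold predictions.
#'
#' @param cv a `maxent_cv`.
#' @param stack the `env_stack`.
#' @param link prediction link.
#' @return A `suitability_grid`.
#' @export
cv_mean_prediction <- function(cv, stack, link = "logistic") {
  preds <- lapply(cv$models, predict_suitability, stack = stack, link = link)
  acc <- Reduce(`+`, lapply(preds, function(p) p$values)) / length(preds)
  out <- preds[[1L]]
  out$values <- acc
  out
}

#' Jackknife of regularized training gain
#'
#' For every variable, fits a model with that variable's features alone
#' and with them omitted, alongside the full model, reporting the three
#' gains. The drop in gain when a variable is omitted ("without" vs full)
#' measures information not contained in the other predictors; see
#' [variable_influence()].
#'
#' @inheritParams crossvalidate
#' @param ... passed to [fit_maxent()].
#' @return data.frame with columns `variable`, `gain_only`, `gain_without`
#'   and attribute `gain_full`.
#' @export
jackknife_gain <- function(presence_cells, background_cells, features, stack,
                           presence_weights = NULL, ...) {
  vars <- feature_variables(features)
  full <- fit_maxent(presence_cells, background_cells, features, stack,
                     presence_weights = presence_weights, ...)
  g_full <- maxent_gain(full)
  res <- lapply(vars, function(v) {
    fo <- features_only(features, v)
    fw <- features_without(features, v)
    g_only <- if (length(fo))
      maxent_gain(fit_maxent(presence_cells, background_cells, fo, stack,
                             presence_weights = presence_weights, ...))
    else NA_real_
    g_without <- if (length(fw))
      maxent_gain(fit_maxent(presence_cells, background_cells, fw, stack,
                             presence_weights = presence_weights, ...))
    else 0
    c(gain_only = g_only, gain_without = g_without)
  })
  out <- data.frame(variable = vars, do.call(rbind, res))
  attr(out, "gain_full") <- g_full
  rownames(out) <- NULL
  out
}

#' Per-variable influence from a jackknife table
#'
#' Influence is the drop in regularized training gain when the variable's
#' features are removed from the full model (floored at 0).
#'
#' @param jack output of [jackknife_gain()].
#' @return Named numeric vector of influence scores.
#' @export
variable_influence <- function(jack) {
  stats::setNames(pmax(0, attr(jack, "gain_full") - jack$gain_without),
                  jack$variable)
}

#' Serialize a fitted model as JSON
#' @param model a `maxent_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maxent_json <- function(model, path) {
  jsonlite::write_json(list(
    features = lapply(unclass(model$features), function(f)
      f[setdiff(names(f), NULL)]),
    lambda = model$lambda, beta = model$beta,
    entropy = model$H, logZ = model$logZ,
    presence_count = model$presence_count,
    background = list(n = length(model$background_cells)),
    converged = model$converged, iterations = model$iterations
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
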