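#' Univariate response curves from cross-validation replicates
#'
#' For each cross-validation replicate, fits a model using only the focal
#' variable's features (the "variable alone" construction: how suitability
#' changes as a function of one environmental variable when it is the only
#' variable under consideration) and evaluates the suitability curve at
#' `n_points` evenly spaced values spanning the background minimum and
#' maximum of that variable.
#'
#' @param presence_cells presence cell indices.
#' @param background_cells background cell indices.
#' @param stack the `env_stack`.
#' @param variable a continuous, non-constant layer name.
#' @param k number of replicates (default 10).
#' @param n_points curve sample density (default 256).
#' @param seed fold seed.
#' @param classes feature classes for the single-variable models (default
#'   linear + quadratic, a smooth unimodal family).
#' @param hinge_knots knots if `"hinge"` is among `classes`.
#' @param presence_weights optional per-record weights.
#' @param link curve link (default logistic).
#' @param ... passed to [fit_maxent()].
#' @return A list of `k` `response_curve` objects (data.frames with
#'   columns `x`, `y` and attributes `variable`, `replicate`).
#' @export
fit_univariate_curves <- function(presence_cells, background_cells, stack,
                                  variable, k = 10, n_points = 256, seed = 1,
                                  classes = c("linear", "quadratic"),
                                  hinge_knots = 16, presence_weights = NULL,
                                  link = "logistic", ...) {
  kinds <- vapply(unclass(stack), `[[`, character(1), "kind")
  if (!variable %in% layer_names(stack))
    stop("unknown variable ", variable, call. = FALSE)
  if (kinds[[variable]] != "continuous")
    stop("`variable` must be continuous (see categorical_profile)", call. = FALSE)
  bg_vals <- stack_values(stack, background_cells)[[variable]]
  rng <- range(bg_vals, na.rm = TRUE)
  if (rng[2L] <= rng[1L])
    stop("degenerate input: `", variable, "` is constant over the background",
         call. = FALSE)
  features <- make_features(stack, classes = classes,
                            hinge_knots = hinge_knots, variables = variable,
                            background_cells = background_cells)
  m <- length(presence_cells)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), m))
  bg_fm <- feature_matrix(features, stack, background_cells)
  xgrid <- seq(rng[1L], rng[2L], length.out = n_points)
  newdata <- stats::setNames(data.frame(xgrid), variable)
  grid_fm <- feature_matrix(features, newdata)
  lapply(seq_len(k), function(fold) {
    train <- folds != fold
    wtr <- if (is.null(presence_weights)) NULL else presence_weights[train]
    mod <- fit_maxent(presence_cells[train], background_cells, features,
                      stack, presence_weights = wtr, bg_fm = bg_fm, ...)
    r <- predict_raw_fm(mod, grid_fm)
    y <- if (link == "logistic") {
      eh <- exp(mod$H) * r
      pmin(1, pmax(0, eh / (1 + eh)))
    } else r
    response_curve(xgrid, y, variable = variable, replicate = fold)
  })
}

#' Construct a response curve
#'
#' @param x strictly increasing sample points spanning the background range
#'   of the variable.
#' @param y suitability at each `x`, in \[0, 1\].
#' @param variable variable name.
#' @param replicate replicate id.
#' @return A `response_curve` data.frame.
#' @export
response_curve <- function(x, y, variable = "", replicate = NA) {
  if (length(x) < 2L || length(x) != length(y))
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("`x` must be strictly increasing", call. = FALSE)
  structure(data.frame(x = x, y = y),
            variable = variable, replicate = replicate,
            class = c("response_curve", "data.frame"))
}

#' Total resource exploitation index of a response curve
#'
#' The trapezoid integral of suitability over the variable's range divided
#' by that range, yielding a \[0, 1\] standardized area under the curve
#' (values near 1: high exploitation across the whole gradient). Invariant
#' to affine rescaling of the x axis.
#'
#' @param curve a `response_curve`.
#' @return Standardized area in \[0, 1\].
#' @export
exploitation_index <- function(curve) {
  rng <- curve$x[length(curve$x)] - curve$x[1L]
  if (rng <= 0) stop("degenerate input: zero x-range", call. = FALSE)
  pracma::trapz(curve$x, curve$y) / rng
}

#' Peak performance of a response curve
#'
#' The maximum suitability attained along the curve.
#'
#' @param curve a `response_curve`.
#' @return Maximum of `y`.
#' @export
peak_performance <- function(curve) max(curve$y)

#' Per-category suitability profile for a categorical variable
#'
#' Fits a model using only the variable's category indicators and reports
#' the predicted suitability of each category, the number of categories
#' with suitability strictly above 0.5, and the maximum (the categorical
#' analogue of exploitation and peak for a gradient that has no ordering).
#'
#' @param presence_cells,background_cells cell indices.
#' @param stack the `env_stack`.
#' @param variable a categorical layer name.
#' @param presence_weights optional per-record weights.
#' @param ... passed to [fit_maxent()].
#' @return List with `profile` (data.frame `code`, `suitability`),
#'   `n_above_half` and `max_suitability`.
#' @export
categorical_profile <- function(presence_cells, background_cells, stack,
                                variable, presence_weights = NULL, ...) {
  kinds <- vapply(unclass(stack), `[[`, character(1), "kind")
  if (kinds[[variable]] != "categorical")
    stop("`variable` must be categorical", call. = FALSE)
  features <- make_features(stack, classes = "categorical",
                            variables = variable,
                            background_cells = background_cells)
  mod <- fit_maxent(presence_cells, background_cells, features, stack,
                    presence_weights = presence_weights, ...)
  codes <- vapply(unclass(features), `[[`, numeric(1), "code")
  newdata <- stats::setNames(data.frame(codes), variable)
  r <- predict_raw_fm(mod, feature_matrix(features, newdata))
  eh <- exp(mod$H) * r
  s <- pmin(1, pmax(0, eh / (1 + eh)))
  list(profile = data.frame(code = codes, suitability = s),
       n_above_half = sum(s > 0.5),
       max_suitability = max(s))
}

#' Tabulate area and peak statistics for sets of response curves
#'
#' @param curves_by_species named list (one element per species), each a
#'   named list (one element per variable) of `response_curve` lists as
#'   returned by [fit_univariate_curves()].
#' @return A `gradient_summary`: list with `replicates` (data.frame
#'   `species`, `variable`, `replicate`, `area`, `peak`), `by_variable`
#'   (means with 95\% t confidence intervals per species x variable) and
#'   `grand` (per-species means across variable means, with 95\% CI).
#' @export
gradient_summary <- function(curves_by_species) {
  rows <- list()
  for (sp in names(curves_by_species)) {
    for (v in names(curves_by_species[[sp]])) {
      for (curve in curves_by_species[[sp]][[v]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, variable = v,
          replicate = attr(curve, "replicate"),
          area = exploitation_index(curve),
          peak = peak_performance(curve))
      }
    }
  }
  gradient_summary_from_replicates(do.call(rbind, rows))
}

#' @rdname gradient_summary
#' @param replicates data.frame with columns `species`, `variable`,
#'   `replicate`, `area`, `peak` (one row per curve), for summaries built
#'   from externally computed statistics.
#' @export
gradient_summary_from_replicates <- function(replicates) {
  reps <- replicates
  ci <- function(x) {
    n <- length(x)
    half <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n) else 0
    c(mean = mean(x), lo = mean(x) - half, hi = mean(x) + half)
  }
  by_var <- do.call(rbind, lapply(
    split(reps, list(reps$species, reps$variable), drop = TRUE),
    function(d) data.frame(species = d$species[1L], variable = d$variable[1L],
                           t(c(area = ci(d$area), peak = ci(d$peak))))))
  rownames(by_var) <- NULL
  grand <- do.call(rbind, lapply(split(by_var, by_var$species), function(d)
    data.frame(species = d$species[1L],
               t(c(area = ci(d$area.mean), peak = ci(d$peak.mean))))))
  rownames(grand) <- NULL
  structure(list(replicates = reps, by_variable = by_var, grand = grand),
            class = "gradient_summary")
}

#' @export
print.gradient_summary <- function(x, ...) {
  cat("<gradient_summary>\n")
  print(x$by_variable, digits = 3)
  cat("grand means (across variable means):\n")
  print(x$grand, digits = 3)
  invisible(x)
}

#' Pooled t comparison of a per-species metric
#'
#' Pooled two-sample t-test (`df = n_A + n_B - 2`) with per-collection
#' means and 95\% t confidence intervals. With zero variance in both
#' collections the t statistic is undefined and only the means are
#' reported.
#'
#' @param values_A,values_B numeric collections (>= 2 values each).
#' @param label metric label.
#' @return List with `label`, `t`, `df`, `p`, `mean_A`, `ci_A`, `mean_B`,
#'   `ci_B`.
#' @export
compare_species_metric <- function(values_A, values_B, label = "") {
  nA <- length(values_A); nB <- length(values_B)
  if (nA < 2 || nB < 2)
    stop("both collections need at least 2 values", call. = FALSE)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * stats::var(values_A) + (nB - 1) * stats::var(values_B)) / df
  if (sp2 <= 0) { t <- NA_real_; p <- NA_real_ }
  else {
    t <- (mean(values_A) - mean(values_B)) / sqrt(sp2 * (1 / nA + 1 / nB))
    p <- 2 * stats::pt(-abs(t), df)
  }
  half <- function(x) stats::qt(0.975, length(x) - 1) *
    stats::sd(x) / sqrt(length(x))
  list(label = label, t = t, df = df, p = p,
       mean_A = mean(values_A), ci_A = half(values_A),
       mean_B = mean(values_B), ci_B = half(values_B))
}

#' Classify species pairs against the two conceptual niche models
#'
#' Per variable, the replicate area and peak values of the two species are
#' compared by pooled t-tests at `alpha`; "equal" means failure to reject.
#' The *standard* pattern is equal areas with a higher specialist peak;
#' the *alternative* pattern is equal peaks with a lower specialist area;
#' every other pattern (including one species higher in both statistics)
#' is classified `"neither"`. The overall verdict reports the per-class
#' counts, the majority class (ties -> `"mixed"`), and the grand-mean
#' comparisons across variable means.
#'
#' @param summary a `gradient_summary` covering both species on the same
#'   variable set.
#' @param specialist,generalist species names as used in `summary`.
#' @param alpha significance level for the equality tests (default 0.05).
#' @return An object of class `model_verdict` with `per_variable`
#'   (data.frame of patterns and classifications), `counts`, `overall`,
#'   and `grand_tests` (area and peak grand-mean comparisons).
#' @export
classify_niche_model <- function(summary, specialist, generalist,
                                 alpha = 0.05) {
  reps <- summary$replicates
  sv <- sort(unique(reps$variable[reps$species == specialist]))
  gv <- sort(unique(reps$variable[reps$species == generalist]))
  if (!identical(sv, gv))
    stop("the two species must be summarized on the same variable set",
         call. = FALSE)
  per_var <- do.call(rbind, lapply(sv, function(v) {
    a_s <- reps$area[reps$species == specialist & reps$variable == v]
    a_g <- reps$area[reps$species == generalist & reps$variable == v]
    p_s <- reps$peak[reps$species == specialist & reps$variable == v]
    p_g <- reps$peak[reps$species == generalist & reps$variable == v]
    ta <- compare_species_metric(a_s, a_g, "area")
    tp <- compare_species_metric(p_s, p_g, "peak")
    area_pat <- if (is.na(ta$p) || ta$p > alpha) "equal_area"
                else if (mean(a_s) > mean(a_g)) "specialist_higher_area"
                else "generalist_higher_area"
    peak_pat <- if (is.na(tp$p) || tp$p > alpha) "equal_peak"
                else if (mean(p_s) > mean(p_g)) "specialist_higher_peak"
                else "generalist_higher_peak"
    cls <- if (area_pat == "equal_area" && peak_pat == "specialist_higher_peak")
      "standard"
    else if (peak_pat == "equal_peak" && area_pat == "generalist_higher_area")
      "alternative"
    else "neither"
    data.frame(variable = v, area_pattern = area_pat, peak_pattern = peak_pat,
               p_area = ta$p, p_peak = tp$p, classification = cls)
  }))
  counts <- table(factor(per_var$classification,
                         levels = c("standard", "alternative", "neither")))
  top <- names(counts)[counts == max(counts)]
  overall <- if (length(top) == 1L) top else "mixed"
  bv <- summary$by_variable
  grand_tests <- if (length(sv) >= 2L) list(
    area = compare_species_metric(
      bv$area.mean[bv$species == specialist],
      bv$area.mean[bv$species == generalist], "grand mean area"),
    peak = compare_species_metric(
      bv$peak.mean[bv$species == specialist],
      bv$peak.mean[bv$species == generalist], "grand mean peak"))
  else NULL                       # grand means need >= 2 variables
  structure(list(per_variable = per_var, counts = c(counts),
                 overall = overall, grand_tests = grand_tests,
                 specialist = specialist, generalist = generalist,
                 alpha = alpha),
            class = "model_verdict")
}

#' @export
print.model_verdict <- function(x, ...) {
  cat(sprintf("<model_verdict> %s (specialist) vs %s (generalist)\n",
              x$specialist, x$generalist))
  print(x$per_variable[c("variable", "area_pattern", "peak_pattern",
                         "classification")], row.names = FALSE)
  cat(sprintf("counts: standard %d, alternative %d, neither %d -> overall '%s'\n",
              x$counts[["standard"]], x$counts[["alternative"]],
              x$counts[["neither"]], x$overall))
  invisible(x)
}

#' Plot response curves for two species on one gradient
#'
#' Overlays the replicate curves of each species (base graphics).
#'
#' @param curves_A,curves_B lists of `response_curve` objects.
#' @param labels species labels for the legend.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_response_curves <- function(curves_A, curves_B,
                                 labels = c("species A", "species B"), ...) {
  xl <- range(curves_A[[1L]]$x, curves_B[[1L]]$x)
  graphics::plot(NA, xlim = xl, ylim = c(0, 1),
                 xlab = attr(curves_A[[1L]], "variable"),
                 ylab = "suitability", ...)
  for (cv in curves_A) graphics::lines(cv$x, cv$y, col = "#2166ac")
  for (cv in curves_B) graphics::lines(cv$x, cv$y, col = "#b2182b", lty = 2)
  graphics::legend("topright", legend = labels, col = c("#2166ac", "#b2182b"),
                   lty = c(1, 2), bty = "n")
  invisible(NULL)
}
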