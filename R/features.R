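#' Build maximum-entropy feature definitions from a stack
#'
#' Feature classes follow the classic maximum-entropy SDM machinery:
#' `linear` and `quadratic` per continuous variable, `product` per
#' continuous pair, `hinge_knots` forward plus `hinge_knots` reverse hinges
#' per continuous variable at evenly spaced knots, and one indicator per
#' observed code of each categorical variable. Threshold features are
#' deliberately unsupported (they allow abrupt step responses and inflate
#' the parameter count). Every feature is min-max scaled into \[0, 1\]
#' using the background cells, and evaluation clamps to the background
#' range.
#'
#' @param stack an `env_stack` (already screened).
#' @param classes subset of `c("linear", "quadratic", "product", "hinge",
#'   "categorical")`.
#' @param hinge_knots number of interior knots per hinge direction.
#' @param variables layer names to use (default: all layers).
#' @param background_cells cells defining the scaling range (default: all
#'   jointly non-nodata cells).
#' @return An object of class `feature_set` (list of feature definitions).
#' @export
make_features <- function(stack,
                          classes = c("linear", "quadratic", "product",
                                      "hinge", "categorical"),
                          hinge_knots = 16, variables = NULL,
                          background_cells = NULL) {
  if ("threshold" %in% classes)
    stop("threshold features are not supported", call. = FALSE)
  allowed <- c("linear", "quadratic", "product", "hinge", "categorical")
  bad <- setdiff(classes, allowed)
  if (length(bad))
    stop("unknown feature class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(variables)) variables <- layer_names(stack)
  if (is.null(background_cells)) background_cells <- complete_cells(stack)
  kinds <- vapply(unclass(stack), `[[`, character(1), "kind")[variables]
  cont <- variables[kinds == "continuous"]
  cats <- variables[kinds == "categorical"]
  vals <- stack_values(stack, background_cells)

  feats <- list()
  add <- function(f) feats[[length(feats) + 1L]] <<- f
  rng <- lapply(cont, function(v) range(vals[[v]], na.rm = TRUE))
  names(rng) <- cont

  for (v in cont) {
    lo <- rng[[v]][1L]; hi <- rng[[v]][2L]
    if (hi <= lo) next                       # constant variable: no features
    if ("linear" %in% classes)
      add(list(class = "linear", vars = v, fmin = lo, fmax = hi,
               label = v))
    if ("quadratic" %in% classes)
      add(list(class = "quadratic", vars = v,
               fmin = min(vals[[v]]^2), fmax = max(vals[[v]]^2),
               label = paste0(v, "^2")))
    if ("hinge" %in% classes && hinge_knots > 0) {
      knots <- seq(lo, hi, length.out = hinge_knots + 2L)
      knots <- knots[-c(1L, hinge_knots + 2L)]
      for (t in knots) {
        add(list(class = "hinge", vars = v, knot = t, dir = "fwd",
                 fmin = 0, fmax = hi - t, label = sprintf("h(%s>%.4g)", v, t)))
        add(list(class = "hinge", vars = v, knot = t, dir = "rev",
                 fmin = 0, fmax = t - lo, label = sprintf("h(%s<%.4g)", v, t)))
      }
    }
  }
  if ("product" %in% classes && length(cont) >= 2L) {
    prs <- utils::combn(cont, 2L)
    for (i in seq_len(ncol(prs))) {
      v1 <- prs[1L, i]; v2 <- prs[2L, i]
      p <- vals[[v1]] * vals[[v2]]
      if (max(p) > min(p))
        add(list(class = "product", vars = c(v1, v2),
                 fmin = min(p), fmax = max(p),
                 label = paste0(v1, "*", v2)))
    }
  }
  if ("categorical" %in% classes) {
    for (v in cats) {
      codes <- sort(unique(vals[[v]][!is.na(vals[[v]])]))
      for (cd in codes)
        add(list(class = "categorical", vars = v, code = cd,
                 fmin = 0, fmax = 1, label = sprintf("%s==%g", v, cd)))
    }
  }
  structure(feats, class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cls <- vapply(unclass(x), `[[`, character(1), "class")
  cat(sprintf("<feature_set> %d feature(s): %s\n", length(x),
              paste(sprintf("%s=%d", names(table(cls)), table(cls)),
                    collapse = ", ")))
  invisible(x)
}

#' Variables a feature set draws on
#' @param features a `feature_set`.
#' @return Character vector of variable names.
#' @export
feature_variables <- function(features) {
  unique(unlist(lapply(unclass(features), `[[`, "vars")))
}

#' Restrict a feature set to (or exclude) given variables
#'
#' `features_only` keeps features whose variables are all within `vars`
#' (used by single-variable response models and the jackknife "only"
#' models); `features_without` removes every feature touching `vars`.
#'
#' @param features a `feature_set`.
#' @param vars variable names.
#' @return A `feature_set`.
#' @export
features_only <- function(features, vars) {
  keep <- vapply(unclass(features), function(f) all(f$vars %in% vars), logical(1))
  structure(unclass(features)[keep], class = "feature_set")
}

#' @rdname features_only
#' @export
features_without <- function(features, vars) {
  keep <- vapply(unclass(features), function(f) !any(f$vars %in% vars), logical(1))
  structure(unclass(features)[keep], class = "feature_set")
}

# Evaluate one feature (raw, unscaled) on a data.frame of variable values.
eval_feature_raw <- function(f, data) {
  switch(f$class,
         linear = data[[f$vars]],
         quadratic = data[[f$vars]]^2,
         product = data[[f$vars[1L]]] * data[[f$vars[2L]]],
         hinge = if (f$dir == "fwd") pmax(0, data[[f$vars]] - f$knot)
                 else pmax(0, f$knot - data[[f$vars]]),
         categorical = as.numeric(!is.na(data[[f$vars]]) &
                                    data[[f$vars]] == f$code),
         stop("unknown feature class ", f$class, call. = FALSE))
}

#' Evaluate a feature set into a scaled feature matrix
#'
#' @param features a `feature_set`.
#' @param data either an `env_stack` (with optional `cells`) or a
#'   data.frame of variable values.
#' @param cells cell indices when `data` is a stack (default all cells).
#' @return Numeric matrix, one column per feature, values clamped to
#'   \[0, 1\]. Rows with nodata in any needed variable yield `NA` (for
#'   continuous features); unseen categorical codes evaluate to 0.
#' @export
feature_matrix <- function(features, data, cells = NULL) {
  if (inherits(data, "env_stack"))
    data <- stack_values(data, cells)
  n <- nrow(data)
  out <- matrix(NA_real_, n, length(features))
  for (j in seq_along(features)) {
    f <- features[[j]]
    raw <- eval_feature_raw(f, data)
    den <- f$fmax - f$fmin
    out[, j] <- if (den > 0) pmin(1, pmax(0, (raw - f$fmin) / den)) else 0
  }
  colnames(out) <- vapply(unclass(features), `[[`, character(1), "label")
  out
}
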