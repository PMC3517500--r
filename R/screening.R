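#' Two-stage environmental variable screening
#'
#' Stage 1 keeps the union of each species' `top_k` most influential
#' variables (variables not in any species' top list are dropped as
#' low-influence). Stage 2 scans the retained variables in descending
#' order of their maximum influence across species and drops any later
#' variable whose absolute Pearson correlation with an already-kept
#' variable exceeds `r_max`, recording the retained partner. The paper-era
#' convention of keeping the "most biologically meaningful" member of a
#' correlated pair is operationalized as keeping the higher-influence
#' member; an explicit `keep` list overrides (those variables are scanned
#' first and never dropped).
#'
#' @param influence named list: one element per species, each a named
#'   numeric vector of per-variable influence scores (e.g. jackknife drop
#'   in regularized training gain, see [variable_influence()]).
#' @param stack an `env_stack` providing the cells over which correlations
#'   are computed (at the modelling resolution).
#' @param top_k per-species influence cut-off (default 10).
#' @param r_max correlation threshold in (0, 1) (default 0.85).
#' @param keep variable names exempt from the correlation drop.
#' @return An object of class `screening_report` with elements `retained`,
#'   `dropped_low_influence`, `dropped_correlated` (named character vector:
#'   dropped -> retained partner), `influence_scores` and `correlations`.
#' @export
screen_variables <- function(influence, stack, top_k = 10, r_max = 0.85,
                             keep = character()) {
  if (!length(influence)) stop("influence scores for at least one species are required",
                               call. = FALSE)
  if (r_max <= 0 || r_max >= 1) stop("`r_max` must be in (0, 1)", call. = FALSE)
  vars <- unique(unlist(lapply(influence, names)))
  if (!length(vars)) stop("influence vectors must be named by variable", call. = FALSE)

  # stage 1: union of per-species top-k
  top_union <- unique(unlist(lapply(influence, function(sc) {
    sc <- sort(sc, decreasing = TRUE)
    names(sc)[seq_len(min(top_k, length(sc)))]
  })))
  dropped_low <- setdiff(vars, top_union)

  # stage 2: greedy correlation pruning by descending max influence
  max_inf <- vapply(top_union, function(v)
    max(vapply(influence, function(sc) if (v %in% names(sc)) sc[[v]] else -Inf,
               numeric(1))), numeric(1))
  order_vars <- top_union[order(-max_inf, top_union)]
  order_vars <- c(intersect(keep, order_vars),
                  setdiff(order_vars, keep))
  dropped_cor <- character()
  if (length(order_vars) >= 2L) {
    cm <- correlation_matrix(stack, variables = intersect(
      order_vars, layer_names(stack)[vapply(unclass(stack), `[[`,
                                            character(1), "kind") == "continuous"]))
    kept <- character()
    for (v in order_vars) {
      partner <- NA_character_
      if (!(v %in% keep) && v %in% rownames(cm)) {
        cand <- intersect(kept, colnames(cm))
        if (length(cand)) {
          rr <- abs(cm[v, cand])
          if (any(rr > r_max)) partner <- cand[which.max(rr)]
        }
      }
      if (is.na(partner)) kept <- c(kept, v)
      else dropped_cor[v] <- partner
    }
    retained <- kept
  } else retained <- order_vars

  structure(list(retained = retained,
                 dropped_low_influence = dropped_low,
                 dropped_correlated = dropped_cor,
                 influence_scores = influence,
                 correlations = if (exists("cm", inherits = FALSE)) cm else NULL),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped_low_influence))
    cat("  dropped (low influence):",
        paste(x$dropped_low_influence, collapse = ", "), "\n")
  if (length(x$dropped_correlated))
    cat("  dropped (correlated):",
        paste(sprintf("%s -> %s", names(x$dropped_correlated),
                      x$dropped_correlated), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a screening report as JSON
#' @param report a `screening_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screening_json <- function(report, path) {
  jsonlite::write_json(list(
    retained = report$retained,
    dropped_low_influence = report$dropped_low_influence,
    dropped_correlated = as.list(report$dropped_correlated),
    influence_scores = report$influence_scores
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
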