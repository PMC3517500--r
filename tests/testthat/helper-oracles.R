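# Independent oracles, deliberately naive: direct loops and closed forms
# kept free of the package's own computational paths.

# Moran's I with rook neighbours by explicit double loop over cell pairs.
morans_i_direct <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  mu <- mean(m)
  num <- 0; wsum <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      ii <- i + d[1L]; jj <- j + d[2L]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        num <- num + (m[i, j] - mu) * (m[ii, jj] - mu)
        wsum <- wsum + 1
      }
    }
  }
  (nr * nc / wsum) * num / sum((m - mu)^2)
}

# Gaussian-kernel record density by an explicit cells x records double loop.
bias_density_direct <- function(xs, ys, occ, sd_km) {
  d <- numeric(length(xs))
  for (c in seq_along(xs)) {
    acc <- 0
    for (r in seq_len(nrow(occ))) {
      d2 <- (xs[c] - occ$lon_km[r])^2 + (ys[c] - occ$lat_km[r])^2
      acc <- acc + exp(-d2 / (2 * sd_km^2))
    }
    d[c] <- acc
  }
  d
}

# Pooled two-sample t from the textbook formula.
pooled_t_direct <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# AUC by brute-force pair counting with half credit for ties.
auc_direct <- function(p, b) {
  wins <- 0
  for (i in seq_along(p)) for (j in seq_along(b)) {
    if (p[i] > b[j]) wins <- wins + 1
    else if (p[i] == b[j]) wins <- wins + 0.5
  }
  wins / (length(p) * length(b))
}

# Penalized maxent objective for explicit lambda, for grid-search oracles:
# L = lambda . pbar - log(mean-free Z over background rows) - sum beta |lambda|
maxent_objective_direct <- function(lambda, Fb, pbar, beta) {
  sum(lambda * pbar) - log(sum(exp(Fb %*% lambda))) - sum(beta * abs(lambda))
}

# Exhaustive grid search of the penalized objective.
maxent_grid_search <- function(Fb, pbar, beta, grid) {
  best <- NULL; best_val <- -Inf
  if (length(pbar) == 1L) {
    for (l1 in grid) {
      v <- maxent_objective_direct(l1, Fb, pbar, beta)
      if (v > best_val) { best_val <- v; best <- l1 }
    }
  } else {
    for (l1 in grid) for (l2 in grid) {
      v <- maxent_objective_direct(c(l1, l2), Fb, pbar, beta)
      if (v > best_val) { best_val <- v; best <- c(l1, l2) }
    }
  }
  best
}

# A tiny two-cell world carrying a single 0/1 gradient.
toy_two_cell <- function() {
  env_stack(raster_layer(matrix(c(0, 1), 1, 2), name = "x"))
}

# Small landscape + species + presences reused across model tests.
toy_world <- function(seed = 42, rows = 32, cols = 32) {
  world <- generate_landscape(rows, cols, n_continuous = 2, n_categorical = 1,
                              smoothness_km = 60, cell_km = 15, seed = seed)
  sp <- virtual_species(list(env1 = response_gaussian(0.9, 0.5, 0.15),
                             env2 = response_gaussian(0.9, 0.5, 0.3)))
  suit <- true_suitability(sp, world)
  occ <- sample_presences(suit, 120, seed = seed + 1)
  pres <- point_to_cell(occ$lon_km, occ$lat_km, world)
  pres <- pres[!is.na(pres)][1:100]
  list(world = world, species = sp, suit = suit, occ = occ, pres = pres,
       bg = complete_cells(world))
}
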