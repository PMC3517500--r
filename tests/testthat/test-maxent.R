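test_that("feature construction yields the expected counts and rejects threshold", {
  st <- generate_landscape(16, 16, 2, 1, smoothness_km = 30, cell_km = 10,
                           n_classes = 3, seed = 6)
  expect_length(make_features(st, classes = "linear", variables = "env1"), 1)
  expect_length(make_features(st, classes = c("linear", "quadratic", "product"),
                              variables = c("env1", "env2")), 5)
  fcat <- make_features(st, classes = "categorical", variables = "cat1")
  expect_length(fcat, length(unique(as.vector(st$cat1$values))))
  fh <- make_features(st, classes = "hinge", hinge_knots = 4, variables = "env1")
  expect_length(fh, 8)  # 4 forward + 4 reverse
  expect_error(make_features(st, classes = c("linear", "threshold")),
               "threshold")
  fm <- feature_matrix(make_features(st), st, complete_cells(st))
  expect_true(all(fm >= 0 & fm <= 1))
})

test_that("bias grids scale to [1, 20] and match the double-loop kernel sum", {
  set.seed(31)
  tmpl <- raster_layer(matrix(0, 40, 40), cell_km = 15)
  occ <- as_occurrence_set(data.frame(
    lon_km = runif(25, 0, 600), lat_km = runif(25, 0, 600),
    uncertainty_km = 0, year = 1990L, source = ""))
  bg <- build_bias_grid(occ, tmpl, kernel_sd_km = 200)
  w <- as.vector(bg$weights$values)
  expect_equal(max(w), 20)
  expect_equal(min(w), 1)
  ctr <- cell_centers(tmpl)
  d <- bias_density_direct(ctr$x, ctr$y, occ, 200)
  w_direct <- 1 + 19 * (d - min(d)) / (max(d) - min(d))
  expect_equal(w, w_direct, tolerance = 1e-10)

  # single record: weight exactly 20 at the nearest cell centre
  one <- as_occurrence_set(data.frame(lon_km = 307, lat_km = 312,
                                      uncertainty_km = 0, year = 1990L,
                                      source = ""))
  b1 <- build_bias_grid(one, tmpl)
  expect_equal(max(b1$weights$values),
               b1$weights$values[point_to_cell(307, 312, tmpl)])
  expect_equal(unname(b1$weights$values[point_to_cell(307, 312, tmpl)]), 20)
  expect_error(build_bias_grid(one[0, ], tmpl), "empty")
})

test_that("a presence distribution equal to the background fits the uniform model", {
  st <- toy_two_cell()
  ft <- make_features(st, classes = "linear")
  m <- fit_maxent(rep(c(1L, 2L), 3), c(1L, 2L), ft, st, beta = 0.1)
  expect_equal(m$lambda, 0)
  s <- predict_suitability(m, st)
  expect_equal(as.vector(s$values), c(0.5, 0.5))
  expect_equal(maxent_gain(m), 0)
})

test_that("the two-cell toy recovers the closed-form lambda = ln 9", {
  st <- toy_two_cell()
  ft <- make_features(st, classes = "linear")
  m <- fit_maxent(rep(2L, 5), c(1L, 2L), ft, st, beta = 0.1)
  expect_equal(m$lambda, log(9), tolerance = 1e-3)
  # 1-D grid-search oracle agrees
  Fb <- matrix(c(0, 1), 2, 1)
  best <- maxent_grid_search(Fb, pbar = 1, beta = 0.1,
                             grid = seq(0, 4, by = 0.002))
  expect_equal(m$lambda, best, tolerance = 2e-3)
  # doubling beta strictly shrinks |lambda|
  m2 <- fit_maxent(rep(2L, 5), c(1L, 2L), ft, st, beta = 0.2)
  expect_lt(abs(m2$lambda), abs(m$lambda))
  expect_equal(m2$lambda, log((1 - 0.2) / 0.2), tolerance = 1e-3)
})

test_that("fitted coefficients match exhaustive grid search on a two-feature toy", {
  x <- seq(0, 1, length.out = 9)
  st <- env_stack(raster_layer(matrix(x, 3, 3), name = "x"))
  ft <- make_features(st, classes = c("linear", "quadratic"))
  pres <- c(3L, 4L, 5L, 6L, 7L, 5L, 5L, 4L)     # clustered mid-gradient
  m <- fit_maxent(pres, 1:9, ft, st, beta = 0.2)
  Fb <- feature_matrix(ft, st, 1:9)
  pbar <- colMeans(Fb[pres, ])
  best <- maxent_grid_search(Fb, pbar, beta = c(0.2, 0.2),
                             grid = seq(-8, 8, by = 0.05))
  expect_lt(max(abs(m$lambda - best)), 0.06)
})

test_that("q stays normalized and the penalized objective never decreases", {
  w <- toy_world()
  ft <- make_features(w$world, classes = c("linear", "quadratic", "hinge"),
                      hinge_knots = 4, variables = c("env1", "env2"))
  m <- fit_maxent(w$pres, w$bg, ft, w$world)
  expect_equal(sum(m$q), 1, tolerance = 1e-8)
  expect_true(all(diff(m$objective) >= -1e-9))
  expect_gte(m$H, 0)
})

test_that("prediction links behave: raw sums to 1, logistic is monotone in raw", {
  w <- toy_world()
  ft <- make_features(w$world, classes = c("linear", "quadratic"),
                      variables = c("env1", "env2"))
  m <- fit_maxent(w$pres, w$bg, ft, w$world)
  raw <- predict_suitability(m, w$world, link = "raw")
  logi <- predict_suitability(m, w$world, link = "logistic")
  rv <- as.vector(raw$values)[w$bg]
  lv <- as.vector(logi$values)[w$bg]
  expect_equal(sum(rv), 1, tolerance = 1e-8)
  expect_true(all(lv >= 0 & lv <= 1))
  expect_identical(order(rv), order(lv))   # strictly increasing transform
})

test_that("AUC equals brute-force pair counting, including ties", {
  expect_equal(auc_presence_background(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  expect_equal(auc_presence_background(c(0.9, 0.95), c(0.1, 0.2)), 1.0)
  expect_equal(auc_presence_background(c(0.3, 0.3), c(0.3, 0.3)), 0.5)
  set.seed(44)
  for (i in 1:3) {
    p <- round(runif(40), 2); b <- round(runif(200), 2)  # rounding forces ties
    expect_equal(auc_presence_background(p, b), auc_direct(p, b))
  }
})

test_that("cross-validation partitions presences once each and is seed-stable", {
  w <- toy_world()
  ft <- make_features(w$world, classes = c("linear", "quadratic"),
                      variables = c("env1", "env2"))
  cv <- crossvalidate(w$pres, w$bg, ft, w$world, k = 10, seed = 5)
  expect_length(cv$models, 10)
  expect_equal(as.vector(table(cv$folds)), rep(length(w$pres) / 10, 10))
  cv2 <- crossvalidate(w$pres, w$bg, ft, w$world, k = 10, seed = 5)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$auc, cv2$auc)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  expect_error(crossvalidate(w$pres[1:5], w$bg, ft, w$world, k = 10), "exceed")
})

test_that("a specialist scores higher cross-validated AUC than a generalist", {
  ok <- 0
  for (seed in c(101, 202, 303)) {
    world <- generate_landscape(32, 32, 3, 0, smoothness_km = 100,
                                cell_km = 15, seed = seed)
    sc <- make_scenario("standard", seed = seed)
    bg <- complete_cells(world)
    ft <- make_features(world, classes = c("linear", "quadratic"),
                        variables = c("env1", "env2", "env3"),
                        background_cells = bg)
    aucs <- sapply(c("specialist", "generalist"), function(role) {
      suit <- true_suitability(sc[[role]], world)
      occ <- sample_presences(suit, 150, seed = seed + 1)
      pres <- point_to_cell(occ$lon_km, occ$lat_km, world)
      crossvalidate(pres, bg, ft, world, k = 5, seed = seed)$mean_auc
    })
    ok <- ok + (aucs["specialist"] > aucs["generalist"])
  }
  expect_gte(ok, 2)
})

test_that("jackknife gains behave at the edges and flag uninformative variables", {
  w <- toy_world()
  ft1 <- make_features(w$world, classes = c("linear", "quadratic"),
                       variables = "env1")
  jk1 <- jackknife_gain(w$pres, w$bg, ft1, w$world)
  expect_equal(jk1$gain_only[jk1$variable == "env1"],
               attr(jk1, "gain_full"), tolerance = 1e-6)

  # species ignores cat1 entirely: its gain_only sits within noise of zero
  ft <- make_features(w$world, classes = c("linear", "quadratic", "categorical"),
                      variables = c("env1", "cat1"))
  jk <- jackknife_gain(w$pres, w$bg, ft, w$world)
  expect_lt(jk$gain_only[jk$variable == "cat1"], 0.1)
  expect_gt(jk$gain_only[jk$variable == "env1"],
            jk$gain_only[jk$variable == "cat1"])
  infl <- variable_influence(jk)
  expect_gt(infl[["env1"]], infl[["cat1"]])
})
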