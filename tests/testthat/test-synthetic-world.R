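test_that("landscape generation is reproducible and validates arguments", {
  a <- generate_landscape(20, 24, 2, 1, smoothness_km = 50, cell_km = 10, seed = 7)
  b <- generate_landscape(20, 24, 2, 1, smoothness_km = 50, cell_km = 10, seed = 7)
  expect_identical(a, b)
  expect_error(generate_landscape(8, 20, 2), "at least 16")
  expect_error(generate_landscape(20, 20, 0), "at least one continuous")
  expect_error(generate_landscape(20, 20, 2, smoothness_km = 1, cell_km = 10),
               "cell size")
})

test_that("continuous layers fill [0,1] and categorical layers use at most k codes", {
  st <- generate_landscape(24, 24, 1, 1, smoothness_km = 40, cell_km = 10,
                           n_classes = 5, seed = 2)
  expect_equal(range(st$env1$values), c(0, 1))
  codes <- unique(as.vector(st$cat1$values))
  expect_lte(length(codes), 5)
  expect_true(all(codes %in% 1:5))
})

test_that("larger smoothing lengths yield higher spatial autocorrelation", {
  rough <- generate_landscape(24, 24, 1, 0, smoothness_km = 10, cell_km = 10,
                              seed = 5)$env1$values
  smooth <- generate_landscape(24, 24, 1, 0, smoothness_km = 100, cell_km = 10,
                               seed = 5)$env1$values
  expect_gt(morans_i_direct(smooth), morans_i_direct(rough))
})

test_that("true suitability matches direct per-cell evaluation", {
  # constant layer at the optimum -> amplitude everywhere
  st <- env_stack(raster_layer(matrix(0.4, 4, 4), name = "env1"))
  sp <- virtual_species(list(env1 = response_gaussian(0.75, 0.4, 0.1)))
  expect_equal(unique(as.vector(true_suitability(sp, st)$values)), 0.75)

  # all-constant-1 responses are rejected; constants alongside a gaussian pass through
  expect_error(virtual_species(list(env1 = response_constant(1))),
               "non-constant")

  # product of two gaussians on linear gradients vs the direct formula
  g1 <- matrix(seq(0, 1, length.out = 16), 4, 4)
  g2 <- matrix(seq(1, 0, length.out = 16), 4, 4, byrow = TRUE)
  st2 <- env_stack(raster_layer(g1, name = "env1"),
                   raster_layer(g2, name = "env2"))
  sp2 <- virtual_species(list(env1 = response_gaussian(0.9, 0.5, 0.2),
                              env2 = response_gaussian(0.8, 0.3, 0.25)),
                         aggregation = "product")
  got <- true_suitability(sp2, st2)$values
  want <- 0.9 * exp(-(g1 - 0.5)^2 / (2 * 0.2^2)) *
    0.8 * exp(-(g2 - 0.3)^2 / (2 * 0.25^2))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
  expect_error(true_suitability(sp2, st), "not in stack")
})

test_that("scenarios satisfy the conceptual-model invariants", {
  for (seed in 1:5) {
    std <- make_scenario("standard", seed = seed)
    rs <- std$specialist$responses$env1
    rg <- std$generalist$responses$env1
    expect_lt(abs(rs$amplitude * rs$width - rg$amplitude * rg$width) /
                (rg$amplitude * rg$width), 0.01)
    expect_gt(rs$amplitude, rg$amplitude)

    alt <- make_scenario("alternative", seed = seed)
    as_ <- alt$specialist$responses$env1
    ag <- alt$generalist$responses$env1
    expect_lt(abs(as_$amplitude - ag$amplitude), 0.01 * ag$amplitude)
    expect_lt(as_$amplitude * as_$width, ag$amplitude * ag$width)
    # generalist constrained by more variables than the specialist
    expect_gt(length(alt$generalist$responses),
              length(alt$specialist$responses))
  }
})

test_that("focal response integrals match the closed-form Gaussian area", {
  sc <- make_scenario("standard", seed = 11)
  x <- seq(-3, 4, length.out = 20001)    # wide range: negligible truncation
  for (role in c("specialist", "generalist")) {
    r <- sc[[role]]$responses$env1
    y <- r$amplitude * exp(-(x - r$optimum)^2 / (2 * r$width^2))
    num <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
    expect_equal(num, r$amplitude * r$width * sqrt(2 * pi), tolerance = 1e-6)
  }
})

test_that("presence sampling follows the suitability x bias law", {
  # point mass: all records at the only suitable cell centre when jitter = 0
  one <- raster_layer(matrix(c(0, 0, 1, 0), 2, 2), cell_km = 10)
  occ <- sample_presences(one, 25, jitter_km = 0, seed = 3)
  expect_equal(nrow(occ), 25)
  expect_true(all(occ$lon_km == 15 & occ$lat_km == 5))

  # two-cell world: frequencies within 3 binomial SE of 0.2/0.8
  two <- raster_layer(matrix(c(0.2, 0.8), 1, 2), cell_km = 1)
  occ2 <- sample_presences(two, 10000, jitter_km = 0, seed = 9)
  n2 <- sum(occ2$lon_km > 1)
  se <- sqrt(10000 * 0.8 * 0.2)
  expect_lt(abs(n2 - 8000), 3 * se)

  # chi-square goodness of fit against suitability x bias on a small grid
  set.seed(1)
  sgrid <- raster_layer(matrix(runif(25, 0.1, 1), 5, 5), cell_km = 1)
  bias <- raster_layer(matrix(runif(25, 0.5, 2), 5, 5), cell_km = 1)
  occ3 <- sample_presences(sgrid, 10000, bias_field = bias, jitter_km = 0,
                           seed = 4)
  counts <- tabulate(attr(occ3, "cell"), nbins = 25)
  p <- as.vector(sgrid$values * bias$values)
  gof <- suppressWarnings(chisq.test(counts, p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)

  expect_error(sample_presences(raster_layer(matrix(0, 2, 2)), 5),
               "degenerate")
})

test_that("sampled records carry years and uncertainties that exercise the filters", {
  s <- raster_layer(matrix(runif(100), 10, 10), cell_km = 10)
  occ <- sample_presences(s, 500, seed = 8)
  expect_true(any(occ$uncertainty_km > 13) && any(occ$uncertainty_km <= 13))
  expect_true(any(occ$year < 1940) && any(occ$year >= 1940))
  expect_identical(occ, sample_presences(s, 500, seed = 8))
})

test_that("range masks follow the suitability threshold", {
  s <- raster_layer(matrix(c(1, 0.5, 0.2, 0.04), 2, 2))
  m <- species_range_mask(s, 0.25)
  expect_equal(as.vector(m$values), c(1, 1, 0, 0))
  m2 <- species_range_mask(s, 0.05)
  expect_equal(sum(m2$values), 3)
})
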