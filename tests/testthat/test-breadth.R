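test_that("standardized breadth hits its endpoints and known values", {
  expect_equal(levins_breadth(raster_layer(matrix(0.7, 20, 20))), 1)
  one <- matrix(0, 20, 20); one[7, 3] <- 0.9
  expect_equal(levins_breadth(raster_layer(one)), 0)
  # s = (0.5, 0.5, 0): B = 2, B_A = 0.5
  expect_equal(levins_breadth(raster_layer(matrix(c(0.5, 0.5, 0), 1, 3))), 0.5)
  expect_error(levins_breadth(raster_layer(matrix(0, 3, 3))), "degenerate")
  expect_error(levins_breadth(raster_layer(matrix(1, 1, 1))), "degenerate")
})

test_that("breadth is scale invariant and respects a region mask", {
  set.seed(77)
  v <- matrix(runif(64), 8, 8)
  s <- raster_layer(v)
  expect_equal(levins_breadth(s), levins_breadth(raster_layer(3.7 * v)))
  mask <- raster_layer(matrix(rep(c(1, 0), each = 32), 8, 8))
  direct <- {
    p <- v[, 1:4] / sum(v[, 1:4])
    (1 / sum(p^2) - 1) / (length(p) - 1)
  }
  expect_equal(levins_breadth(s, mask), direct)
})

test_that("transferring mass from a low to a high cell never increases breadth", {
  set.seed(15)
  for (rep in 1:20) {
    s <- runif(30)
    b0 <- levins_breadth(raster_layer(matrix(s, 1, 30)))
    i_low <- which.min(s); i_hi <- which.max(s)
    d <- runif(1, 0, s[i_low])
    s2 <- s; s2[i_low] <- s2[i_low] - d; s2[i_hi] <- s2[i_hi] + d
    b1 <- levins_breadth(raster_layer(matrix(s2, 1, 30)))
    expect_lte(b1, b0 + 1e-12)
  }
})

test_that("null breadth distributions are seeded, sized and bounded", {
  w <- toy_world()
  ft <- make_features(w$world, classes = c("linear", "quadratic"),
                      variables = c("env1", "env2"))
  mask <- species_range_mask(w$suit, 0.25)
  nulls <- null_breadth_distribution(mask, w$world, n_points = 40,
                                     features = ft, n_rep = 10, seed = 3)
  expect_length(nulls, 10)
  expect_true(all(nulls >= 0 & nulls <= 1))
  expect_identical(nulls, null_breadth_distribution(mask, w$world, 40, ft,
                                                    n_rep = 10, seed = 3))
  expect_error(null_breadth_distribution(mask, w$world, 1e6, ft, n_rep = 2),
               "exceeds")
})

test_that("random-presence models over a uniform world stay near-uniform in breadth", {
  # with no environmental signal in the species, null models fitted to
  # random points concentrate only through sampling noise
  w <- toy_world()
  ft <- make_features(w$world, classes = c("linear", "quadratic"),
                      variables = c("env1", "env2"))
  all_mask <- raster_layer(matrix(1, 32, 32), cell_km = 15)
  nulls <- null_breadth_distribution(all_mask, w$world, n_points = 100,
                                     features = ft, n_rep = 10, seed = 21)
  expect_gt(mean(nulls), 0.95)
})

test_that("the breadth difference test reproduces the pooled-t plumbing", {
  set.seed(5)
  base <- rnorm(100, 0, 0.01)
  rA <- breadth_result(0.5, 0.5 - base, species = "lynx-like")
  rB <- breadth_result(0.5, 0.5 - base, species = "bobcat-like")
  same <- breadth_difference_test(rA, rB)
  expect_equal(same$t, 0)
  expect_equal(same$df, 198)
  expect_equal(same$verdict, "indistinguishable")

  dA <- rnorm(100, -0.06, 0.01); dB <- rnorm(100, 0.05, 0.01)
  rA2 <- breadth_result(0, -dA, species = "sp")
  rB2 <- breadth_result(0, -dB, species = "gen")
  cmp <- breadth_difference_test(rA2, rB2)
  expect_equal(cmp$df, 198)
  expect_equal(cmp$t, pooled_t_direct(dA, dB), tolerance = 1e-12)
  expect_equal(cmp$verdict, "sp narrower")

  # zero pooled variance: undefined t, verdict from the means
  rC <- breadth_result(0.4, rep(0.5, 10), species = "c")
  rD <- breadth_result(0.6, rep(0.5, 10), species = "d")
  deg <- breadth_difference_test(rC, rD)
  expect_true(is.na(deg$t))
  expect_equal(deg$verdict, "c narrower")
})
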