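ramp_curve <- function(n = 101, x0 = 2, x1 = 7) {
  response_curve(seq(x0, x1, length.out = n),
                 seq(0, 1, length.out = n), variable = "v", replicate = 1)
}

test_that("the exploitation index is a range-normalized trapezoid area", {
  flat <- response_curve(seq(0, 1, length.out = 50), rep(0.5, 50))
  expect_equal(exploitation_index(flat), 0.5)
  expect_equal(exploitation_index(ramp_curve()), 0.5)   # triangle
  # affine rescaling of x leaves the index unchanged
  a <- ramp_curve(x0 = 2, x1 = 7)
  b <- response_curve(3 * a$x - 10, a$y)
  expect_equal(exploitation_index(a), exploitation_index(b))
})

test_that("trapezoid areas agree with a 10x finer Riemann sum on smooth curves", {
  set.seed(33)
  for (i in 1:5) {
    mu <- runif(1, 0.3, 0.7); sg <- runif(1, 0.05, 0.3); A <- runif(1, 0.3, 1)
    f <- function(x) A * exp(-(x - mu)^2 / (2 * sg^2))
    x <- seq(0, 1, length.out = 256)
    coarse <- exploitation_index(response_curve(x, f(x)))
    xf <- seq(0, 1, length.out = 2560)
    fine <- sum(f(xf[-1] - diff(xf) / 2) * diff(xf))
    expect_equal(coarse, fine, tolerance = 1e-3)
  }
})

test_that("peak performance is the curve maximum and bounds the area", {
  expect_equal(peak_performance(response_curve(1:3, c(0.1, 0.7, 0.3))), 0.7)
  expect_equal(peak_performance(response_curve(1:4, rep(0.42, 4))), 0.42)
  set.seed(10)
  for (i in 1:20) {
    cv <- response_curve(sort(runif(30)) + seq(0, 1e-6, length.out = 30),
                         runif(30))
    expect_gte(peak_performance(cv), exploitation_index(cv))
    expect_lte(peak_performance(cv), 1)
    expect_gte(exploitation_index(cv), 0)
  }
})

test_that("univariate curves rise along the gradient that drives the presences", {
  # two-cell toy: all presences at x = 1, so the curve must increase
  st <- toy_two_cell()
  curves <- fit_univariate_curves(rep(2L, 10), c(1L, 2L), st, "x", k = 2,
                                  n_points = 16, seed = 1,
                                  classes = "linear", beta = 0.1)
  expect_length(curves, 2)
  for (cv in curves) {
    expect_gt(cv$y[nrow(cv)], cv$y[1])
    expect_equal(range(cv$x), c(0, 1))   # spans the background range
  }
})

test_that("curve replication matches the fold count and rejects bad variables", {
  w <- toy_world()
  curves <- fit_univariate_curves(w$pres, w$bg, w$world, "env1", k = 10,
                                  seed = 2)
  expect_length(curves, 10)
  expect_equal(vapply(curves, function(cv) attr(cv, "replicate"), numeric(1)),
               1:10)
  rng <- range(stack_values(w$world, w$bg)$env1)
  expect_equal(range(curves[[1]]$x), rng)
  expect_error(fit_univariate_curves(w$pres, w$bg, w$world, "cat1"),
               "continuous")
  const <- env_stack(raster_layer(matrix(0.5, 16, 16), name = "c"))
  expect_error(fit_univariate_curves(rep(5L, 10), 1:256, const, "c"),
               "constant")
})

test_that("categorical profiles count strict exceedances of one half", {
  w <- toy_world()
  prof <- categorical_profile(w$pres, w$bg, w$world, "cat1")
  expect_equal(nrow(prof$profile),
               length(unique(as.vector(w$world$cat1$values))))
  expect_equal(prof$n_above_half, sum(prof$profile$suitability > 0.5))
  expect_equal(prof$max_suitability, max(prof$profile$suitability))
  expect_true(all(prof$profile$suitability >= 0 &
                    prof$profile$suitability <= 1))
})

test_that("species metric comparisons reproduce the pooled-t plumbing", {
  same <- compare_species_metric(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  set.seed(6)
  a <- rnorm(9, 0.6, 0.05); b <- rnorm(9, 0.63, 0.05)
  cmp <- compare_species_metric(a, b)
  expect_equal(cmp$df, 16)
  expect_equal(cmp$t, pooled_t_direct(a, b), tolerance = 1e-12)
  expect_equal(cmp$ci_A, qt(0.975, 8) * sd(a) / 3, tolerance = 1e-12)
  expect_error(compare_species_metric(1, c(1, 2)), "at least 2")
})

test_that("the classifier maps the three canonical patterns correctly", {
  fake_summary <- function(a_s, a_g, p_s, p_g, sd = 0.002, n = 10) {
    set.seed(1)
    reps <- rbind(
      data.frame(species = "sp", variable = "v", replicate = 1:n,
                 area = rnorm(n, a_s, sd), peak = rnorm(n, p_s, sd)),
      data.frame(species = "gen", variable = "v", replicate = 1:n,
                 area = rnorm(n, a_g, sd), peak = rnorm(n, p_g, sd)))
    gradient_summary_from_replicates(reps)
  }
  std <- classify_niche_model(fake_summary(0.4, 0.4, 0.8, 0.5), "sp", "gen")
  expect_equal(std$per_variable$classification, "standard")
  alt <- classify_niche_model(fake_summary(0.3, 0.5, 0.7, 0.7), "sp", "gen")
  expect_equal(alt$per_variable$classification, "alternative")
  both <- classify_niche_model(fake_summary(0.6, 0.4, 0.8, 0.5), "sp", "gen")
  expect_equal(both$per_variable$classification, "neither")
  expect_error(classify_niche_model(fake_summary(0.4, 0.4, 0.8, 0.5),
                                    "sp", "missing"), "same variable set")
})

test_that("the species with the larger true focal area earns the larger estimated index", {
  # alternative scenarios engineer a larger generalist focal area; the
  # estimated exploitation index must preserve that ordering across seeds
  wins <- 0
  for (seed in c(11, 22, 33)) {
    r <- suppressMessages(run_scenario_analysis("alternative", seed = seed,
                                                rows = 48, cols = 48,
                                                n_records = 250, n_rep = 2,
                                                k = 5))
    reps <- r$gradient$replicates
    wins <- wins + (mean(reps$area[reps$species == "generalist"]) >
                      mean(reps$area[reps$species == "specialist"]))
  }
  expect_gte(wins, 3)
})
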