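test_that("welch_t reproduces closed-form hand computations", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4) # equal n, equal variance: n1 + n2 - 2
  expect_equal(w$ci[1] + w$ci[2], 2 * (w$mean_x - w$mean_y)) # symmetric CI

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t(1, c(1, 2)), "two finite")
})

test_that("welch_t agrees with the incomplete-beta oracle to 1e-10", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(sample(3:20, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    w <- welch_t(x, y)
    o <- welch_closed_form(x, y)
    expect_equal(w$t, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p, o$p, tolerance = 1e-10)
    expect_equal(w$ci, o$ci, tolerance = 1e-10)
  }
})

test_that("welch_t is antisymmetric and location/scale equivariant", {
  set.seed(3)
  x <- rnorm(8, 2)
  y <- rnorm(11, 3, 2)
  w <- welch_t(x, y)
  flipped <- welch_t(y, x)
  expect_equal(flipped$t, -w$t)
  expect_equal(flipped$p, w$p)

  shifted <- welch_t(x + 100, y + 100)
  expect_equal(shifted$t, w$t)
  expect_equal(shifted$p, w$p)

  scaled <- welch_t(3 * x, 3 * y)
  expect_equal(scaled$t, w$t)
  expect_equal(scaled$ci, 3 * w$ci)
})

test_that("group samples reconstructed from a Welch tuple round-trip it", {
  g <- welch_groups_from_summary(5, 5, 106.6, 32.2, t = 10.78, df = 5.45)
  w <- welch_t(g$x, g$y)
  expect_equal(w$t, 10.78, tolerance = 1e-8)
  expect_equal(w$df, 5.45, tolerance = 1e-8)
  expect_equal(mean(g$x), 106.6)
  expect_equal(sd(g$x), g$sd1)

  # a df above n1 + n2 - 2 is impossible for any variance pair
  expect_error(
    welch_groups_from_summary(3, 3, 126.9, 66.9, t = 2.93, df = 5.97),
    "internally inconsistent"
  )
})

test_that("lipid quantification follows the standard-ratio formula", {
  expect_equal(quantify_class(100, 100, 250), 250) # equal areas -> standard
  expect_equal(quantify_class(200, 100, 100), 200) # ratio 2 doubles
  expect_equal(quantify_class(0, 100, 250), 0)
  expect_error(quantify_class(10, 0, 100), "positive")
})

test_that("mass correction standardizes residuals orthogonal to mass", {
  mass <- c(40, 48, 55, 61, 70, 75)
  exact <- 2 + 0.5 * mass
  expect_equal(mass_correct(exact, mass), rep(0, 6))

  set.seed(21)
  lipid <- 2 + 0.5 * mass + rnorm(6, 0, 2)
  z <- mass_correct(lipid, mass)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sum(z * mass), 0, tolerance = 1e-8) # orthogonal to mass
  expect_equal(sd(z), 1, tolerance = 0.2) # ~unit scale

  expect_error(mass_correct(lipid, rep(50, 6)), "constant")
  expect_error(mass_correct(lipid[1:2], mass[1:2]), "at least 3")
})

test_that("a simulated morph effect is detected downstream in most runs", {
  hits <- vapply(1:40, function(s) {
    li <- simulate_lipid_table(n_per_group = 16, morph_effect = 6, seed = s)
    z <- mass_correct(total_lipid(li), li$abdomen_mass_mg)
    welch_t(z[li$morph == "alba"], z[li$morph == "orange"])$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("square aggregation averages integer counts only", {
  expect_equal(aggregate_squares(c(60, 70, 80)), 70)
  expect_equal(aggregate_squares(55), 55)
  expect_error(aggregate_squares(c(60.5, 70)), "integers")
  expect_error(aggregate_squares(numeric(0)), "no square counts")
})
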