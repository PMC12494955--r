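test_that("scalar expectile solves the balance equation", {
  expect_equal(scalar_expectile(c(0, 10), 0.5), 5)
  expect_equal(scalar_expectile(c(0, 10), 0.9), 9, tolerance = 1e-9)
  expect_equal(scalar_expectile(rep(3.7, 8), 0.23), 3.7)
  expect_error(scalar_expectile(numeric(0), 0.5), "empty")
  expect_error(scalar_expectile(1:3, 1.2), "tau")

  # independent oracle: numeric minimization of the asymmetric squared loss
  loss <- function(e, x, tau) {
    w <- ifelse(x > e, tau, 1 - tau)
    sum(w * (x - e)^2)
  }
  set.seed(42)
  for (tau in c(0.05, 0.3, 0.5, 0.8, 0.95)) {
    x <- rnorm(40, sd = 3)
    opt <- optimize(loss, range(x), x = x, tau = tau, tol = 1e-12)$minimum
    expect_equal(scalar_expectile(x, tau), opt, tolerance = 1e-6)
  }
})

test_that("curve fit on a single age cluster reproduces the scalar expectile", {
  set.seed(7)
  # a band far narrower than the 1-year knot resolution; n large enough that
  # the O(sd/sqrt(n)) gap between the local fit and the scalar expectile is
  # inside the oracle tolerance
  age <- runif(20000, 49.99, 50.01)
  y <- rnorm(20000, 2, 0.1)
  for (tau in c(0.05, 0.5, 0.95)) {
    fit <- fit_expectile_curve(age, y, tau, lambda = 1e-8)
    expect_equal(predict(fit, 50), scalar_expectile(y, tau),
                 tolerance = 1e-3)
  }
})

test_that("fits are translation and scale equivariant and monotone in tau", {
  set.seed(8)
  age <- runif(300, 10, 90)
  y <- 0.2 + 0.002 * age + rnorm(300, 0, 0.05)
  grid <- 20:80
  base <- lapply(c(0.05, 0.5, 0.95), function(tau) {
    predict(fit_expectile_curve(age, y, tau), grid)
  })
  # monotone in tau at every grid age (well-sampled data; pre-repair)
  expect_true(all(base[[1]] <= base[[2]] + 1e-8))
  expect_true(all(base[[2]] <= base[[3]] + 1e-8))
  # translation: y + c shifts the curve by exactly c
  shifted <- predict(fit_expectile_curve(age, y + 3.5, 0.5), grid)
  expect_equal(shifted, base[[2]] + 3.5, tolerance = 1e-8)
  # scale: k * y multiplies the curve by k
  scaled <- predict(fit_expectile_curve(age, 4 * y, 0.95), grid)
  expect_equal(scaled, 4 * base[[3]], tolerance = 1e-8)
})

test_that("the median-expectile curve recovers a known linear trend", {
  set.seed(9)
  n <- 2000
  age <- runif(n, 0, 50)
  y <- 2 * age + rnorm(n, 0, 2)
  fit <- fit_expectile_curve(age, y, 0.5, lambda = 0.1)
  grid <- 5:45 # interior ages
  # Monte-Carlo band: local-mean standard error at the realized density
  expect_lt(max(abs(predict(fit, grid) - 2 * grid)), 0.5)
  expect_true(fit$converged)
})

test_that("concave constraint forces non-positive second differences", {
  set.seed(10)
  age <- runif(400, 0, 80)
  y <- 0.001 * (age - 40)^2 + rnorm(400, 0, 0.05) # convex-shaped data
  fit <- fit_expectile_curve(age, y, 0.5, shape = "concave")
  grid <- ceiling(min(age)):floor(max(age))
  d2 <- diff(predict(fit, grid), differences = 2)
  expect_true(all(d2 <= 1e-8))
  # and the symmetric convex constraint on the same data is near-exact
  fitc <- fit_expectile_curve(age, y, 0.5, shape = "convex")
  expect_true(all(diff(predict(fitc, grid), differences = 2) >= -1e-8))
})

test_that("reference curve sets respect tau ordering and subset agreement", {
  # zero noise, zero field bias: both field subsets see the same deterministic
  # trajectory, so their mid curves must agree on shared grid ages
  specs <- default_structure_specs()["left_hippocampus"]
  specs$left_hippocampus$noise_sd <- 0
  cfg <- synthetic_config(n_cn = 400, structures = specs, noise_sd = 0,
                          fraction_3T = 0.5, seed = 21)
  nc <- normalize_by_icv(generate_cohort(cfg))
  cs15 <- fit_reference_curves(nc, "left_hippocampus", smoothing = "none",
                               subset = "1.5T", lambda = 1e-8, quiet = TRUE)
  cs3 <- fit_reference_curves(nc, "left_hippocampus", smoothing = "none",
                              subset = "3T", lambda = 1e-8, quiet = TRUE)
  shared <- intersect(cs15$age_grid, cs3$age_grid)
  v15 <- evaluate_curve(cs15, shared, 0.5)
  v3 <- evaluate_curve(cs3, shared, 0.5)
  expect_equal(v15, v3, tolerance = 1e-6)

  # tau ordering holds at every grid age on noisy data
  cs <- fit_reference_curves(
    normalize_by_icv(generate_cohort(synthetic_config(n_cn = 500, seed = 22))),
    "left_hippocampus", quiet = TRUE
  )
  expect_true(all(cs$values[, 1] <= cs$values[, 2]))
  expect_true(all(cs$values[, 2] <= cs$values[, 3]))
  expect_error(
    fit_reference_curves(
      normalize_by_icv(generate_cohort(
        synthetic_config(n_cn = 50, n_ad = 10, seed = 3))),
      "left_hippocampus"
    ),
    "controls"
  )
})

test_that("lower-bound coverage matches the scalar-expectile oracle", {
  cfg <- synthetic_config(n_cn = 3000, seed = 23)
  nc <- normalize_by_icv(generate_cohort(cfg))
  cs <- fit_reference_curves(nc, "left_hippocampus", quiet = TRUE)
  ok <- nc$records$age >= min(cs$age_grid) & nc$records$age <= max(cs$age_grid)
  value <- nc$normalized$left_hippocampus[ok]
  lower <- evaluate_curve(cs, nc$records$age[ok], 0.05)
  observed <- 100 * mean(value < lower)
  # oracle: coverage below the scalar 0.05-expectile of the generator noise
  set.seed(99)
  noise <- rnorm(2e5, 0, 0.02)
  oracle <- 100 * mean(noise < scalar_expectile(noise, 0.05))
  expect_lt(abs(observed - oracle), 2)
})

test_that("curve evaluation interpolates linearly and refuses extrapolation", {
  cs <- make_curveset(ages = 0:10, lower = (0:10) - 1, mid = 0:10,
                      upper = (0:10) + 1)
  expect_equal(evaluate_curve(cs, 4, 0.5), 4)
  expect_equal(evaluate_curve(cs, 4.5, 0.5), 4.5) # midpoint = neighbor mean
  expect_equal(evaluate_curve(cs, c(0, 10), 0.95), c(1, 11))
  expect_error(evaluate_curve(cs, -0.5, 0.5), "extrapolation")
  expect_error(evaluate_curve(cs, 10.5, 0.5), "extrapolation")
  expect_error(evaluate_curve(cs, 5, 0.25), "not in curve set")
})
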