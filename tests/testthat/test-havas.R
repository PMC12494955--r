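test_that("reference self-normalization yields mean 0, sd 1 composites", {
  co <- generate_cohort(synthetic_config(n_cn = 400, seed = 61))
  nc <- normalize_by_icv(co)
  st <- compute_reference_stats(nc)
  for (side in c("left", "right")) {
    sc <- havas_score(nc, st, side)
    expect_equal(mean(sc$normalized), 0, tolerance = 1e-12)
    expect_equal(sd(sc$normalized), 1, tolerance = 1e-12)
    # raw composite identity holds record by record
    expect_equal(sc$raw, sc$z_hippocampus + sc$z_amygdala - sc$z_ventricle)
  }
  expect_equal(st$n_reference, 400)

  # shuffling record order leaves the statistics unchanged
  perm <- sample(nrow(co))
  st2 <- compute_reference_stats(
    normalize_by_icv(subset_cohort(co, perm)))
  expect_equal(st2$structure_stats$mean, st$structure_stats$mean)
  expect_equal(st2$composite_stats$sd, st$composite_stats$sd)
})

test_that("degenerate and invalid reference cohorts are refused", {
  one <- generate_cohort(synthetic_config(n_cn = 1, seed = 62))
  clones <- subset_cohort(one, rep(1, 50))
  clones$subject_id <- sprintf("c%02d", 1:50)
  expect_error(
    compute_reference_stats(as_brain_cohort(as.data.frame(clones))),
    "zero standard deviation"
  )
  mixed <- generate_cohort(synthetic_config(n_cn = 40, n_ad = 5, seed = 63))
  expect_error(compute_reference_stats(mixed), "CN records only")
  expect_error(
    compute_reference_stats(generate_cohort(
      synthetic_config(n_cn = 10, seed = 64))),
    "at least 30"
  )
})

test_that("HAVAs scores follow the z-score formula and sign structure", {
  co <- generate_cohort(synthetic_config(n_cn = 200, seed = 65))
  st <- compute_reference_stats(normalize_by_icv(co))
  ss <- st$structure_stats
  get <- function(name, what) ss[[what]][ss$structure == name]

  # a subject exactly at the reference means scores (0, 0, 0) -> raw 0
  at_mean <- cohort_from_normalized(
    as.data.frame(setNames(
      lapply(ss$structure, function(s) get(s, "mean")), ss$structure)),
    age = 50
  )
  sc <- havas_score(at_mean, st, "left")
  expect_equal(sc$z_hippocampus, 0, tolerance = 1e-12)
  expect_equal(sc$raw, 0, tolerance = 1e-12)

  # z = (-2, -1.5, +1.5) -> raw -5
  vals <- as.data.frame(setNames(
    lapply(ss$structure, function(s) get(s, "mean")), ss$structure))
  vals$left_hippocampus <- get("left_hippocampus", "mean") -
    2 * get("left_hippocampus", "sd")
  vals$left_amygdala <- get("left_amygdala", "mean") -
    1.5 * get("left_amygdala", "sd")
  vals$left_inferior_lateral_ventricle <-
    get("left_inferior_lateral_ventricle", "mean") +
    1.5 * get("left_inferior_lateral_ventricle", "sd")
  sc2 <- havas_score(cohort_from_normalized(vals, age = 50), st, "left")
  expect_equal(sc2$raw, -5, tolerance = 1e-9)

  # atrophic pattern scores lower than its mirror image
  mirror <- vals
  mirror$left_hippocampus <- get("left_hippocampus", "mean") +
    2 * get("left_hippocampus", "sd")
  mirror$left_amygdala <- get("left_amygdala", "mean") +
    1.5 * get("left_amygdala", "sd")
  mirror$left_inferior_lateral_ventricle <-
    get("left_inferior_lateral_ventricle", "mean") -
    1.5 * get("left_inferior_lateral_ventricle", "sd")
  sc3 <- havas_score(cohort_from_normalized(mirror, age = 50), st, "left")
  expect_lt(sc2$raw, sc3$raw)

  # missing structure named in the error
  small <- cohort_from_normalized(
    data.frame(left_hippocampus = 0.2), age = 50)
  expect_error(havas_score(small, st, "left"), "left_amygdala")
})

test_that("raw HAVAs is invariant to rescaling a structure everywhere", {
  co <- generate_cohort(synthetic_config(n_cn = 150, seed = 66))
  st <- compute_reference_stats(normalize_by_icv(co))
  sc <- havas_score(normalize_by_icv(co), st, "left")
  scaled <- as.data.frame(co)
  scaled$left_hippocampus <- scaled$left_hippocampus * 1.37
  co2 <- as_brain_cohort(scaled, cohort_structures(co))
  st2 <- compute_reference_stats(normalize_by_icv(co2))
  sc2 <- havas_score(normalize_by_icv(co2), st2, "left")
  expect_equal(sc2$raw, sc$raw, tolerance = 1e-9)
})

test_that("HAVAs reference curves are flat-ish for age-free scores and calibrated", {
  co <- generate_cohort(synthetic_config(n_cn = 3000, seed = 67))
  nc <- normalize_by_icv(co)
  st <- compute_reference_stats(nc)
  curves <- havas_reference_curves(nc, st, side = "left", smoothing = "none",
                                   quiet = TRUE)
  expect_true(all(curves$values[, 1] <= curves$values[, 2]))
  expect_true(all(curves$values[, 2] <= curves$values[, 3]))

  scores <- havas_score(nc, st, "left")
  ok <- scores$age >= min(curves$age_grid) & scores$age <= max(curves$age_grid)
  path <- havas_pathology(scores[ok, ], curves)
  # CN-only coverage below the lower curve tracks the scalar-expectile oracle
  set.seed(1)
  z <- rnorm(2e5)
  oracle <- 100 * mean(z < scalar_expectile(z, 0.05))
  expect_lt(abs(path$rate_cn - oracle), 2)
  expect_true(is.na(path$rate_ad))
  expect_null(path$report)

  # strict inequality at the bound
  flat <- make_flat_curveset(-1.6, 0, 1.6, structure = "havas_left")
  sc_edge <- scores[1, ]
  sc_edge$age <- 50
  sc_edge$normalized <- -1.6
  class(sc_edge) <- c("havas_scores", "data.frame")
  expect_false(havas_pathology(sc_edge, flat)$calls$atrophied)
})
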