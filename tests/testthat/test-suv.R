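test_that("decay factor follows the half-life law", {
  expect_equal(decay_factor(67.71, 0), 1.0)
  expect_equal(decay_factor(67.71, 67.71), 0.5)
  expect_equal(decay_factor(109.77, 2 * 109.77), 0.25)
  expect_equal(decay_factor(109.77, 20), 0.8813, tolerance = 1e-4)
  expect_error(decay_factor(67.71, -5), "scan precedes injection")
  expect_error(decay_factor(0, 5), "half_life_min")
})

test_that("activity-to-SUV conversion matches hand calculation", {
  g <- voxel_grid(array(5000, c(4, 4, 4)), spacing = c(2, 2, 2))
  acq <- simple_acq(dose = 1.5e8, weight = 70000, dt_min = 45,
                    half_life = 67.71)
  suv <- activity_to_suv(g, acq)
  # 5000 * 70000 / (1.5e8 * exp(-log(2) * 45 / 67.71)) = 3.699
  expect_equal(suv$values[1, 1, 1], 3.699, tolerance = 1e-3)
  expect_identical(suv$units, "SUV")
  expect_identical(dim(suv$values), dim(g$values))
})

test_that("SUV is linear in activity and weight, inverse-linear in dose, and exact at dt = 0", {
  vals <- array(runif(4^3, 100, 9000), c(4, 4, 4))
  g <- voxel_grid(vals, spacing = c(2, 2, 2))
  acq0 <- simple_acq(dt_min = 0)
  expect_equal(activity_to_suv(g, acq0)$values,
               vals * 70000 / 1.5e8)
  acq <- simple_acq(dt_min = 30)
  base <- activity_to_suv(g, acq)$values
  acq2w <- simple_acq(dt_min = 30, weight = 140000)
  expect_equal(activity_to_suv(g, acq2w)$values, 2 * base)
  acq2d <- simple_acq(dt_min = 30, dose = 3e8)
  expect_equal(activity_to_suv(g, acq2d)$values, base / 2)
  g2 <- voxel_grid(2 * vals, spacing = c(2, 2, 2))
  expect_equal(activity_to_suv(g2, acq)$values, 2 * base)
})

test_that("SUV increases with uptake interval for fixed activity", {
  g <- voxel_grid(array(1000, c(3, 3, 3)), spacing = c(2, 2, 2))
  suvs <- vapply(c(0, 10, 30, 60, 120), function(dt)
    activity_to_suv(g, simple_acq(dt_min = dt))$values[1], numeric(1))
  expect_true(all(diff(suvs) > 0))
})

test_that("double conversion and broken metadata are rejected", {
  g <- voxel_grid(array(1, c(3, 3, 3)), spacing = c(2, 2, 2))
  acq <- simple_acq()
  suv <- activity_to_suv(g, acq)
  expect_error(activity_to_suv(suv, acq), "already in SUV")
  expect_error(simple_acq(dt_min = -10), "precedes injection")
  expect_error(acquisition_record("x", NA, 1e8, 7e4,
                                  Sys.time(), Sys.time()),
               "metadata absent.*half_life_min")
  expect_error(acquisition_record("x", 67.71, -1, 7e4,
                                  Sys.time(), Sys.time()),
               "strictly positive")
})

test_that("decay conventions: precorrected input and inverse exponent", {
  g <- voxel_grid(array(1000, c(3, 3, 3)), spacing = c(2, 2, 2))
  acq <- simple_acq(dt_min = 45)
  plain <- 1000 * 70000 / 1.5e8
  expect_equal(activity_to_suv(g, acq, decay_to = "none")$values[1], plain)
  df <- decay_factor(67.71, 45)
  expect_equal(activity_to_suv(g, acq, decay_to = "injection")$values[1],
               plain / df)
  expect_equal(activity_to_suv(g, acq, decay_to = "inverse")$values[1],
               plain * df)
})

test_that("phantom activity encoding round-trips through SUV conversion", {
  b <- generate_phantom(small_phantom_spec(rng_seed = 11L))
  for (t in list(c("activity_a", "acq_a", "suv_scene_a"),
                 c("activity_b", "acq_b", "suv_scene_b"))) {
    suv <- activity_to_suv(b[[t[1]]], b[[t[2]]])
    ref <- if (t[3] == "suv_scene_a") b$suv_scene_a$values else NULL
    if (!is.null(ref)) {
      rel <- abs(suv$values - ref) / pmax(abs(ref), 1e-9)
      expect_lt(max(rel[ref != 0]), 1e-6)
    }
  }
})

test_that("acquisition sidecars round-trip through JSON", {
  acq <- simple_acq()
  f <- tempfile(fileext = ".json")
  write_acquisition_json(acq, f)
  back <- read_acquisition_json(f)
  expect_equal(back$half_life_min, acq$half_life_min)
  expect_equal(back$injected_dose_Bq, acq$injected_dose_Bq)
  expect_equal(uptake_interval_min(back), uptake_interval_min(acq))
  expect_error(read_acquisition_json(tempfile()), "metadata absent")
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(tracer = "x"), bad, auto_unbox = TRUE)
  expect_error(read_acquisition_json(bad), "metadata absent.*half_life_min")
})
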