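test_that("rigid transforms compose and invert to identity", {
  set.seed(7)
  for (i in 1:10) {
    tr <- rigid_transform(runif(3, -0.4, 0.4), runif(3, -20, 20),
                          runif(3, -10, 10))
    M <- transform_matrix(tr)
    expect_lt(max(abs(crossprod(M[1:3, 1:3]) - diag(3))), 1e-12)
    comp <- compose_transforms(invert_transform(tr), tr)
    expect_lt(max(abs(transform_matrix(comp) - diag(4))), 1e-9)
    # Euler extraction round-trips the rotation matrix
    R <- petbtv:::euler_to_matrix(tr$angles_rad)
    expect_lt(max(abs(petbtv:::euler_to_matrix(
      petbtv:::matrix_to_euler(R)) - R)), 1e-12)
  }
})

test_that("transform JSON serialisation round-trips", {
  tr <- rigid_transform(c(0.1, -0.05, 0.2), c(3, -4, 5), c(1, 2, 3))
  f <- tempfile(fileext = ".json")
  write_transform_json(tr, f)
  back <- read_transform_json(f)
  expect_equal(back$angles_rad, tr$angles_rad)
  expect_equal(back$translation_mm, tr$translation_mm)
  expect_equal(back$centre_mm, tr$centre_mm)
})

test_that("resampling with the identity on the same geometry is a no-op", {
  sc <- cube_scene()
  out <- resample(sc$grid, rigid_transform(), sc$grid, "trilinear")
  expect_equal(out$values, sc$grid$values, tolerance = 1e-12)
})

test_that("nearest-neighbour keeps masks binary and trilinear stays within range", {
  sc <- cube_scene()
  tr <- rigid_transform(c(0.05, -0.03, 0.08), c(5, -3, 2))
  m_out <- resample(sc$cube, tr, sc$grid, "nearest")
  expect_true(all(m_out$values %in% c(TRUE, FALSE)))
  g_out <- resample(sc$grid, tr, sc$grid, "trilinear")
  expect_gte(min(g_out$values), min(sc$grid$values) - 1e-12)
  expect_lte(max(g_out$values), max(sc$grid$values) + 1e-12)
  # a constant grid stays constant inside the mapped support
  const <- voxel_grid(array(3, dim(sc$grid$values)), sc$grid$spacing,
                      sc$grid$origin, units = "SUV")
  c_out <- resample(const, tr, const, "trilinear", fill = NA)
  expect_true(all(abs(c_out$values[!is.na(c_out$values)] - 3) < 1e-12))
  expect_error(resample(sc$grid, tr, sc$grid, "cubic"))
})

test_that("mirroring is an involution, preserves volume and reflects centroids", {
  dims <- c(20, 16, 12)
  arr <- array(FALSE, dims)
  arr[3:6, 5:9, 4:7] <- TRUE   # off-centre cube
  m <- pet_mask(arr, spacing = c(2, 2, 2), origin = -(dims - 1),
                label = "cube")
  mm <- mirror_across_midsagittal(m)
  expect_equal(mask_voxels(mm), mask_voxels(m))
  back <- mirror_across_midsagittal(mm)
  expect_identical(back$values, m$values)
  # centroid reflects across the central plane of the left-right axis
  cen <- colMeans(which(m$values, arr.ind = TRUE))
  cen_m <- colMeans(which(mm$values, arr.ind = TRUE))
  expect_equal(cen_m[1], dims[1] + 1 - cen[1])
  expect_equal(cen_m[2:3], cen[2:3])
  # a symmetric mask is its own mirror
  sym <- array(FALSE, dims)
  sym[9:12, 5:8, 4:6] <- TRUE  # centred on the plane between 10 and 11
  ms <- pet_mask(sym, spacing = c(2, 2, 2), origin = -(dims - 1))
  expect_identical(mirror_across_midsagittal(ms)$values, ms$values)
})

test_that("brain masking excludes voxels without biasing region statistics", {
  sc <- cube_scene()
  masked <- apply_brain_mask(sc$grid, sc$brain)
  st_full <- region_stats(masked, sc$cube)
  st_raw <- region_stats(sc$grid, sc$cube)
  expect_equal(st_full$suv_mean, st_raw$suv_mean)
  # uniform grid: halving the brain does not change the mean
  uni <- voxel_grid(array(2, dim(sc$grid$values)), sc$grid$spacing,
                    sc$grid$origin, units = "SUV")
  half <- sc$brain$values
  half[1:(dim(half)[1] / 2), , ] <- FALSE
  half_mask <- pet_mask(half, reference = uni, label = "half")
  st <- region_stats(apply_brain_mask(uni, half_mask), half_mask)
  expect_equal(st$suv_mean, 2)
  # a region reaching outside the brain errors instead of averaging zeros
  outside <- pet_mask(array(TRUE, dim(uni$values)), reference = uni)
  expect_error(region_stats(apply_brain_mask(uni, half_mask), outside),
               "outside the valid")
  # geometry mismatch is rejected
  other <- voxel_grid(array(1, c(8, 8, 8)), c(2, 2, 2))
  expect_error(apply_brain_mask(other, sc$brain), "geometry")
})

test_that("fallback brain mask recovers the phantom brain sphere", {
  b <- generate_phantom(small_phantom_spec(rng_seed = 3L))
  suv <- activity_to_suv(b$activity_a, b$acq_a)
  est <- estimate_brain_mask(suv)
  expect_gt(dice(est, b$brain_mask), 0.95)
})
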