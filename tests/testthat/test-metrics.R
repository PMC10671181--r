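test_that("region statistics match a per-voxel oracle on random grids", {
  set.seed(17)
  for (rep in 1:5) {
    dims <- c(16, 16, 16)
    g <- voxel_grid(array(rnorm(prod(dims), 2, 0.5), dims), c(2, 2, 2),
                    units = "SUV")
    m <- pet_mask(array(runif(prod(dims)) < 0.3, dims), reference = g)
    if (mask_voxels(m) == 0) next
    st <- region_stats(g, m, background_suv_mean = 0.8)
    vals <- c()
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3])
      if (m$values[i, j, k]) vals <- c(vals, g$values[i, j, k])
    expect_equal(st$suv_mean, mean(vals))
    expect_equal(st$suv_max, max(vals))
    expect_equal(st$volume_mm3, length(vals) * 8)
    expect_equal(st$tbr_mean, mean(vals) / 0.8)
    expect_equal(st$tbr_max, max(vals) / 0.8)
    expect_gte(st$suv_max, st$suv_mean)
  }
})

test_that("region statistics handle uniform and degenerate regions", {
  sc <- cube_scene(background = 2, cube_value = 2)
  st <- region_stats(sc$grid, sc$cube)
  expect_equal(st$suv_mean, 2)
  expect_equal(st$suv_max, 2)
  empty <- pet_mask(array(FALSE, dim(sc$grid$values)), reference = sc$grid,
                    label = "nothing")
  expect_error(region_stats(sc$grid, empty), "empty region")
  # 1000 voxels at 2x2x2 mm -> 8000 mm^3
  dims <- c(10, 10, 10)
  g <- voxel_grid(array(1, dims), c(2, 2, 2))
  m <- pet_mask(array(TRUE, dims), reference = g)
  expect_equal(region_stats(g, m)$volume_mm3, 8000)
})

test_that("TBR images are exact voxel-wise quotients", {
  sc <- cube_scene(background = 1, cube_value = 2)
  tbr <- tbr_image(sc$grid, 0.5)
  expect_identical(tbr$units, "TBR")
  expect_equal(max(tbr$values), 4)
  st_suv <- region_stats(sc$grid, sc$cube)
  st_tbr <- region_stats(tbr, sc$cube)
  expect_equal(st_tbr$suv_mean, st_suv$suv_mean / 0.5)
  expect_equal(st_tbr$suv_max, st_suv$suv_max / 0.5)
  # scaling the SUV image scales TBR linearly
  g2 <- sc$grid; g2$values <- 3 * g2$values
  expect_equal(tbr_image(g2, 0.5)$values, 3 * tbr$values)
  expect_error(tbr_image(sc$grid, 0), "positive")
})

test_that("Dice coefficient satisfies its identities", {
  sc <- cube_scene()
  a <- sc$cube
  expect_equal(dice(a, a), 1)
  disj <- array(FALSE, dim(a$values)); disj[1:2, 1:2, 1:2] <- TRUE
  d <- pet_mask(disj, reference = sc$grid)
  expect_equal(dice(a, d), 0)
  expect_equal(dice(a, d), dice(d, a))
  # |a| = |b| = 8, overlap 4 -> 0.5
  x <- array(FALSE, c(8, 8, 8)); x[1:2, 1:2, 1:2] <- TRUE
  y <- array(FALSE, c(8, 8, 8)); y[1:2, 1:2, 2:3] <- TRUE
  gx <- pet_mask(x, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  gy <- pet_mask(y, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_equal(dice(gx, gy), 0.5)
  e <- pet_mask(array(FALSE, c(8, 8, 8)), spacing = c(1, 1, 1),
                origin = c(0, 0, 0))
  expect_error(dice(e, e), "both masks are empty")
})

test_that("volumetric ratios reproduce the printed per-patient values", {
  expect_equal(volumetric_ratio(59725, 39765), 1.50, tolerance = 5e-3)
  expect_equal(volumetric_ratio(9483, 28136), 0.337, tolerance = 5e-3)
  expect_equal(volumetric_ratio(100, 100), 1)
  expect_equal(volumetric_ratio(3, 7) * volumetric_ratio(7, 3), 1)
  expect_error(volumetric_ratio(5, 0), "positive")
})

test_that("organ ratios and the theranostic screen follow the cutoffs", {
  mk <- function(mean, max) structure(
    list(label = "r", n_voxels = 10L, volume_mm3 = 80,
         suv_mean = mean, suv_max = max, tbr_mean = NA, tbr_max = NA),
    class = "region_stats")
  r <- organ_ratios(mk(2, 7.04), mk(1, 7.04))
  expect_equal(r$mean_ratio, 2)
  expect_equal(r$max_ratio, 1)
  r2 <- organ_ratios(mk(2, 7.04), mk(2, 14.08))
  expect_equal(r2$mean_ratio, 1)
  expect_equal(r2$max_ratio, 0.5)
  expect_error(organ_ratios(mk(2, 3), mk(0, 3)), "positive")

  # patient-1-like values fail both cutoffs
  q <- theranostic_qualification(tlr_max = 1.07, tsg_max = 0.49)
  expect_false(q$qualifies)
  expect_length(q$reasons, 2)
  # boundary inclusive
  expect_true(theranostic_qualification(1.5, 1.0)$qualifies)
  q3 <- theranostic_qualification(2.0, 0.5)
  expect_false(q3$qualifies)
  expect_match(q3$reasons, "TSG")
  expect_length(q3$reasons, 1)
})

test_that("masked voxel-wise correlation matches cor.test and detects affine relations", {
  set.seed(9)
  dims <- c(12, 12, 12)
  a <- voxel_grid(array(rnorm(prod(dims), 2, 0.4), dims), c(2, 2, 2),
                  units = "SUV")
  m <- pet_mask(array(runif(prod(dims)) < 0.5, dims), reference = a)
  # affine relation -> r = 1
  b <- a; b$values <- 2 * a$values + 1
  expect_equal(voxelwise_correlation(a, b, m)$r, 1, tolerance = 1e-12)
  # independent images -> r near zero, p agrees with cor.test
  b2 <- voxel_grid(array(rnorm(prod(dims)), dims), c(2, 2, 2),
                   units = "SUV")
  res <- voxelwise_correlation(a, b2, m)
  expect_lt(abs(res$r), 0.1)
  ct <- cor.test(a$values[m$values], b2$values[m$values])
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p_two_sided, ct$p.value, tolerance = 1e-12)
  # constant input errors
  flat <- voxel_grid(array(1, dims), c(2, 2, 2), units = "SUV")
  expect_error(voxelwise_correlation(flat, b2, m), "constant")
})

test_that("phantom pipeline recovers the copula correlation without misalignment", {
  b <- generate_phantom(phantom_spec(
    grid_shape = c(72, 72, 72), spacing_mm = c(2, 2, 2),
    brain_radius_mm = 65, tumour_centre_mm = c(20, 8, 5),
    tumour_radii_mm = c(25, 22, 19), cross_tracer_rho = 0.51,
    misalignment = rigid_transform(), rng_seed = 77L))
  suv_a <- activity_to_suv(b$activity_a, b$acq_a)
  suv_b <- activity_to_suv(b$activity_b, b$acq_b)
  res <- voxelwise_correlation(suv_a, suv_b, b$tumour_mask)
  expect_lt(abs(res$r - 0.51), 0.05)
  expect_lt(res$p_two_sided, 1e-10)
})
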