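test_that("noise-free piecewise-constant scene segments to the exact cube", {
  sc <- cube_scene(background = 1, cube_value = 5)
  cfg <- segmentation_config(initial_suv_threshold = 2.2,
                             tbr_threshold = 1.7)
  seg <- segment_btv(sc$grid, sc$brain, cfg)
  expect_false(seg$no_avid_lesion)
  expect_equal(seg$background_suv_mean, 1.0)
  expect_identical(seg$btv$values, sc$cube$values)
  # BTV equals the analytic superlevel set {SUV/background >= threshold}
  analytic <- sc$brain$values & (sc$grid$values / 1.0 >= 1.7)
  expect_identical(seg$btv$values, analytic)
})

test_that("an all-background image reports no avid lesion, not an error", {
  sc <- cube_scene(background = 1, cube_value = 1)
  cfg <- segmentation_config(2.2, 1.7)
  seg <- segment_btv(sc$grid, sc$brain, cfg)
  expect_true(seg$no_avid_lesion)
  expect_equal(mask_voxels(seg$btv), 0)
  expect_true(is.na(seg$background_suv_mean))
})

test_that("BTV and control VOI respect containment and disjointness", {
  b <- generate_phantom(small_phantom_spec(rng_seed = 12L))
  suv <- apply_brain_mask(activity_to_suv(b$activity_a, b$acq_a),
                          b$brain_mask)
  seg <- segment_btv(suv, b$brain_mask, default_segmentation_config("fet"))
  expect_true(all(!seg$btv$values | b$brain_mask$values))
  expect_true(all(!seg$control_voi$values | b$brain_mask$values))
  expect_equal(sum(seg$btv$values & seg$control_voi$values), 0)
})

test_that("raising the TBR threshold never enlarges the BTV", {
  b <- generate_phantom(small_phantom_spec(rng_seed = 13L))
  suv <- apply_brain_mask(activity_to_suv(b$activity_a, b$acq_a),
                          b$brain_mask)
  sizes <- vapply(c(1.3, 1.7, 2.0, 2.3), function(thr) {
    cfg <- segmentation_config(2.2, thr)
    mask_voxels(segment_btv(suv, b$brain_mask, cfg)$btv)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("seed points select their component and invalid seeds error", {
  sc <- cube_scene(background = 1, cube_value = 5)
  cfg <- segmentation_config(2.2, 1.7)
  inside <- which(sc$cube$values, arr.ind = TRUE)[1, ]
  seg <- segment_btv(sc$grid, sc$brain, cfg, seed_point = inside)
  expect_identical(seg$btv$values, sc$cube$values)
  cold <- which(sc$brain$values & !sc$cube$values, arr.ind = TRUE)[1, ]
  expect_error(segment_btv(sc$grid, sc$brain, cfg, seed_point = cold),
               "avid component")
})

test_that("segmentation recovers the phantom tumour under noise", {
  dices <- verrs <- numeric(4)
  for (i in 1:4) {
    spec <- small_phantom_spec(
      background_mean = c(1.0, 1.0), background_sd = c(0.05, 0.05),
      tumour_tbr_target = c(5, 5), noise_sd = 0.05,
      misalignment = rigid_transform(), rng_seed = 40L + i)
    b <- generate_phantom(spec)
    suv <- apply_brain_mask(activity_to_suv(b$activity_a, b$acq_a),
                            b$brain_mask)
    seg <- segment_btv(suv, b$brain_mask,
                       default_segmentation_config("psma"))
    dices[i] <- dice(seg$btv, b$tumour_mask)
    verrs[i] <- abs(mask_volume(seg$btv) - mask_volume(b$tumour_mask)) /
      mask_volume(b$tumour_mask)
  }
  expect_true(all(dices >= 0.90))
  expect_true(all(verrs <= 0.10))
})

test_that("empty control VOI demands a manual mask and a manual mask overrides", {
  # tumour mirrored onto itself: a cube symmetric about the mid-sagittal
  # plane (i -> 33 - i) mirrors to itself, which is avid, so the automatic
  # control VOI is empty
  sc <- cube_scene(cube_idx = list(15:18, 14:18, 14:18))
  cfg <- segmentation_config(2.2, 1.7)
  expect_error(segment_btv(sc$grid, sc$brain, cfg), "control")
  manual <- array(FALSE, dim(sc$grid$values))
  manual[8:11, 14:18, 14:18] <- TRUE
  manual <- pet_mask(manual & sc$brain$values, reference = sc$grid,
                     label = "control")
  seg <- segment_btv(sc$grid, sc$brain, cfg, control_mask = manual)
  expect_equal(seg$background_suv_mean, 1.0)
  expect_identical(seg$btv$values, sc$cube$values)
})

test_that("overlap mask is the voxel-wise conjunction", {
  sc <- cube_scene()
  a <- sc$cube
  expect_identical(overlap_mask(a, a)$values, a$values)
  shifted <- array(FALSE, dim(a$values))
  shifted[21:25, 15:19, 15:19] <- TRUE
  b <- pet_mask(shifted, reference = sc$grid, label = "b")
  ov <- overlap_mask(a, b)
  expect_lte(mask_voxels(ov), min(mask_voxels(a), mask_voxels(b)))
  disj <- array(FALSE, dim(a$values)); disj[1:2, 1:2, 1:2] <- TRUE
  d <- pet_mask(disj, reference = sc$grid)
  expect_equal(mask_voxels(overlap_mask(a, d)), 0)
  other <- pet_mask(array(FALSE, c(8, 8, 8)), spacing = c(2, 2, 2),
                    origin = c(0, 0, 0))
  expect_error(overlap_mask(a, other), "geometry")
})

test_that("region masks load, align by nearest neighbour, and reject non-binary files", {
  sc <- cube_scene()
  f <- tempfile(fileext = ".nii.gz")
  write_grid_nifti(sc$cube, f)
  m <- load_region_mask(f, sc$grid, "tumour")
  expect_identical(m$values, sc$cube$values)
  # offset grid: resampled via nearest, stays binary
  off <- voxel_grid(array(0, dim(sc$grid$values)), sc$grid$spacing,
                    sc$grid$origin + c(1.1, -0.7, 0.4), units = "SUV")
  m2 <- load_region_mask(f, off, "tumour")
  expect_true(all(m2$values %in% c(TRUE, FALSE)))
  expect_gt(mask_voxels(m2), 0)
  fc <- tempfile(fileext = ".nii.gz")
  write_grid_nifti(sc$grid, fc)   # continuous values
  expect_error(load_region_mask(fc, sc$grid), "not binary")
})
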