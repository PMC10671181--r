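# Shared fixtures, built in code at test time.

# Small, fast phantom used across tests; overrides via ...
small_phantom_spec <- function(..., rng_seed = 1L) {
  phantom_spec(grid_shape = c(40, 40, 40), spacing_mm = c(3.5, 3.5, 3.5),
               brain_radius_mm = 60, tumour_centre_mm = c(24, 10, 5),
               tumour_radii_mm = c(14, 12, 10), rng_seed = rng_seed, ...)
}

# Piecewise-constant test scene: uniform background inside a spherical
# brain, a cuboid tumour at a known voxel range. Returns grid + masks.
cube_scene <- function(dims = c(32, 32, 32), spacing = c(4, 4, 4),
                       background = 1, cube_value = 5,
                       cube_idx = list(20:24, 14:18, 14:18)) {
  origin <- -(dims - 1) / 2 * spacing
  grid <- voxel_grid(array(0, dims), spacing, origin, units = "SUV")
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  w <- idx
  for (d in 1:3) w[, d] <- origin[d] + (idx[, d] - 1) * spacing[d]
  brain <- array(rowSums(w^2) <= 55^2, dims)
  v <- array(0, dims)
  v[brain] <- background
  cube <- array(FALSE, dims)
  cube[cube_idx[[1]], cube_idx[[2]], cube_idx[[3]]] <- TRUE
  cube <- cube & brain
  v[cube] <- cube_value
  grid$values <- v
  list(grid = grid,
       brain = pet_mask(brain, reference = grid, label = "brain"),
       cube = pet_mask(cube, reference = grid, label = "tumour"))
}

# Acquisition record with simple defaults for direct SUV arithmetic.
simple_acq <- function(dose = 1.5e8, weight = 70000, dt_min = 45,
                       half_life = 67.71, tracer = "PSMA-617") {
  t0 <- as.POSIXct("2020-06-01 10:00:00", tz = "UTC")
  acquisition_record(tracer, half_life, dose, weight, t0, t0 + dt_min * 60)
}

# Exhaustive signed-rank oracle: two-sided p by enumerating all 2^n sign
# assignments of the (midrank-tied) absolute-difference ranks.
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_pos <- as.vector(signs %*% r)
  min(1, 2 * mean(w_pos <= w_obs + 1e-9))
}
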