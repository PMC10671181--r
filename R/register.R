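#' Rigid co-registration of two volumes
#'
#' Estimates the 6-parameter (3D Euler) rigid transform mapping `moving`
#' into the space of `fixed` by maximising a similarity metric -- by
#' default normalised mutual information (the entropy ratio
#' `(H(a)+H(b))/H(a,b)`) computed from a joint intensity histogram -- over
#' a multi-resolution pyramid with derivative-free optimisation. The
#' normalised form is used because plain mutual information rewards
#' transforms that push background out of the overlap region. Rotation is
#' parameterised about the geometric centre of the fixed grid.
#'
#' Numerical choices: both volumes are smoothed with a separable 1-2-1
#' kernel at every level before the metric is evaluated (this removes the
#' asymmetry between a crisp reference and an interpolation-smoothed
#' acquisition, which otherwise biases histogram metrics by a fraction of
#' a voxel); pyramid levels are block-mean downsampled, never below 16
#' voxels per axis; the coarsest level is seeded by a deterministic grid
#' search over whole-voxel translations; each level runs Nelder-Mead with
#' one restart to rebuild a collapsed simplex. The procedure contains no
#' randomness, so identical inputs give identical transforms.
#'
#' @param moving,fixed [voxel_grid()] objects with overlapping fields of
#'   view and at least two distinct intensity levels each.
#' @param initial optional [rigid_transform()] starting estimate.
#' @param metric `"mi"` (normalised mutual information, the default),
#'   `"ncc"` (negative absolute normalised cross-correlation) or `"mse"`
#'   (mean squared difference; same-tracer images only).
#' @param levels maximum number of pyramid levels (downsampling factors
#'   `2^(levels-1) ... 1`, capped by the 16-voxel floor).
#' @param bins histogram bins per axis for the MI metric (halved on levels
#'   with few samples).
#' @param max_samples maximum number of fixed-grid voxels used per metric
#'   evaluation (fixed-stride subsampling; deterministic).
#' @param mask optional [pet_mask()] on the fixed grid restricting metric
#'   sampling to a region of interest (e.g. an eroded brain mask). High
#'   contrast object edges dominate an unmasked metric and their
#'   interpolation asymmetry can bias the optimum by a fraction of a
#'   degree; masking to the object interior removes that bias when the
#'   interior carries enough structure. Ignored (with a warning) when it
#'   leaves fewer than 500 samples at some level.
#' @param seed_search_voxels half-width, in coarse voxels, of the
#'   translation seed search at the coarsest level (0 disables).
#' @param seed_rotation_deg step, in degrees, of the Euler-angle seed
#'   search at the coarsest level (0 disables).
#' @param seed_rotation_steps half-width of the rotation seed search in
#'   steps per axis (2 with a 5 degree step scans -10..10 degrees).
#' @param maxit Nelder-Mead iteration cap per level.
#' @param reltol relative convergence tolerance on the metric.
#' @return a [rigid_transform()] mapping moving to fixed world space, with
#'   attributes `metric_value`, `evaluations` and `metric`.
#' @export
register_rigid <- function(moving, fixed, initial = NULL,
                           metric = c("mi", "ncc", "mse"),
                           levels = 3, bins = 32, max_samples = 40000,
                           mask = NULL,
                           seed_search_voxels = 3, seed_rotation_deg = 5,
                           seed_rotation_steps = 2, maxit = 800,
                           reltol = 1e-8) {
  stopifnot(is_voxel_grid(moving), is_voxel_grid(fixed))
  metric <- match.arg(metric)
  if (stats::sd(moving$values) == 0 || stats::sd(fixed$values) == 0)
    stop("degenerate (constant) image: registration metric undefined")
  if (!is.null(initial) && !inherits(initial, "rigid_transform"))
    stop("`initial` must be a rigid_transform")
  if (!is.null(mask)) {
    stopifnot(is_pet_mask(mask))
    check_same_geometry(mask, fixed, "sampling mask and fixed grid")
  }

  centre <- grid_centre(fixed)
  par <- if (is.null(initial)) rep(0, 6)
         else c(initial$angles_rad, initial$translation_mm)
  par_init <- par
  finest_objective <- NULL

  factors <- 2^((levels - 1):0)
  factors <- unique(pmin(factors,
                         max(1, 2^floor(log2(min(dim(fixed$values)) / 16)))))
  total_evals <- 0L
  final <- NULL

  for (li in seq_along(factors)) {
    f <- factors[li]
    fx <- smooth_121(if (f > 1) downsample_grid(fixed, f) else fixed)
    mv <- smooth_121(if (f > 1) downsample_grid(moving, f) else moving)

    dims <- dim(fx$values)
    stride <- max(1L, ceiling((prod(dims) / max_samples)^(1 / 3)))
    idx <- as.matrix(expand.grid(i = seq(1L, dims[1], by = stride),
                                 j = seq(1L, dims[2], by = stride),
                                 k = seq(1L, dims[3], by = stride)))
    if (!is.null(mask)) {
      mk <- if (f > 1) {
        mg <- downsample_grid(
          voxel_grid(array(as.numeric(mask$values), dim(mask$values)),
                     mask$spacing, mask$origin, mask$orientation,
                     units = "binary"), f)
        mg$values > 0.5
      } else mask$values
      keep <- mk[idx]
      if (sum(keep) >= 500) idx <- idx[keep, , drop = FALSE]
      else warning("sampling mask leaves < 500 samples at level ", li,
                   "; ignoring mask at this level")
    }
    world <- voxel_to_world(fx, idx)
    fv <- fx$values[idx]
    lbins <- if (nrow(idx) < 8000) max(8L, bins %/% 2L) else bins
    fix_rng <- range(fx$values)
    mov_rng <- range(mv$values)

    objective <- function(p) {
      tr <- rigid_transform(p[1:3], p[4:6], centre)
      ci <- world_to_voxel(mv, apply_transform(invert_transform(tr), world))
      s <- sample_grid_at(mv$values, dim(mv$values), ci, "trilinear", NA)
      ok <- !is.na(s)
      if (sum(ok) < max(50, 0.1 * length(s))) return(1e6)
      similarity_cost(fv[ok], s[ok], metric, lbins, fix_rng, mov_rng)
    }

    if (li == 1L && seed_search_voxels > 0) {
      step <- fx$spacing[1]
      offs <- seq(-seed_search_voxels, seed_search_voxels) * step
      grid <- as.matrix(expand.grid(tx = offs, ty = offs, tz = offs))
      costs <- apply(grid, 1, function(tt)
        objective(c(par[1:3], par[4:6] + tt)))
      total_evals <- total_evals + nrow(grid)
      par[4:6] <- par[4:6] + grid[which.min(costs), ]
    }
    rot_scan <- function(par, step_deg) {
      offs <- seq(-seed_rotation_steps, seed_rotation_steps) *
        step_deg * pi / 180
      grid <- as.matrix(expand.grid(ax = offs, ay = offs, az = offs))
      costs <- apply(grid, 1, function(aa)
        objective(c(par[1:3] + aa, par[4:6])))
      total_evals <<- total_evals + nrow(grid)
      par[1:3] <- par[1:3] + grid[which.min(costs), ]
      par
    }
    tra_scan <- function(par, step_mm, half = 2) {
      offs <- seq(-half, half) * step_mm
      grid <- as.matrix(expand.grid(tx = offs, ty = offs, tz = offs))
      costs <- apply(grid, 1, function(tt)
        objective(c(par[1:3], par[4:6] + tt)))
      total_evals <<- total_evals + nrow(grid)
      par[4:6] <- par[4:6] + grid[which.min(costs), ]
      par
    }
    nm_pass <- function(par) {
      opt <- stats::optim(par, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol,
                                         parscale = c(rep(0.05, 3),
                                                      rep(3, 3))))
      total_evals <<- total_evals + opt$counts[["function"]]
      opt
    }

    if (li == length(factors) && seed_rotation_deg > 0 &&
        seed_rotation_steps > 0) {
      # rotation is identified by fine-scale structure, so the global
      # angle search runs at the finest level, alternated with whole- and
      # half-voxel translation re-scans and a simplex descent: rotation
      # and translation compensate each other on near-symmetric scenes,
      # so neither scan alone suffices
      for (round in 1:2) {
        par <- rot_scan(par, seed_rotation_deg)
        par <- tra_scan(par, fx$spacing[1])
        opt <- nm_pass(par)
        par <- opt$par
      }
      for (step_deg in seed_rotation_deg / 3^(1:2))
        par <- rot_scan(par, step_deg)
      par <- tra_scan(par, fx$spacing[1] / 2, half = 1)
    }

    opt <- nm_pass(par)
    par <- opt$par

    if (li == length(factors)) {
      finest_objective <- objective
      # final polish: cyclic one-dimensional (Brent) line searches with
      # shrinking brackets; deterministic and free of simplex stalls
      pol <- coordinate_polish(objective, par,
                               angle_brackets = c(2, 0.6, 0.2) * pi / 180,
                               transl_brackets = c(1.5, 0.5, 0.15),
                               tol = max(reltol, 1e-6))
      par <- pol$par
      total_evals <- total_evals + pol$evaluations
      final <- pol
    } else {
      final <- list(value = opt$value, converged = TRUE)
    }
  }
  if (!final$converged)
    stop(sprintf(
      "registration did not converge: final metric %.6g after %d evaluations",
      final$value, total_evals))
  # on a metric plateau (e.g. perfectly aligned inputs) prefer the
  # starting estimate over an equally-scoring wander; the band absorbs
  # the sub-resolution gains a binned histogram metric can show for
  # epsilon offsets around an exact optimum
  init_cost <- finest_objective(par_init)
  if (init_cost <= final$value + 1e-4 * max(1, abs(final$value))) {
    par <- par_init
    final$value <- init_cost
  }
  out <- rigid_transform(par[1:3], par[4:6], centre)
  attr(out, "metric_value") <- final$value
  attr(out, "evaluations") <- total_evals
  attr(out, "metric") <- metric
  out
}

# Cyclic coordinate descent: one Brent line search per parameter per
# sweep, with per-sweep shrinking brackets. Declares convergence when a
# whole sweep improves the cost by less than `tol` (relative).
coordinate_polish <- function(objective, par, angle_brackets,
                              transl_brackets, tol = 1e-8,
                              max_extra_sweeps = 5) {
  evals <- 0L
  value <- objective(par)
  evals <- evals + 1L
  converged <- FALSE
  n_sweeps <- length(angle_brackets)
  sweep_widths <- c(seq_len(n_sweeps), rep(n_sweeps, max_extra_sweeps))
  improvement <- Inf
  for (s in sweep_widths) {
    before <- value
    for (ci in 1:6) {
      half <- if (ci <= 3) angle_brackets[s] else transl_brackets[s]
      f1 <- function(v) { p <- par; p[ci] <- v; objective(p) }
      o <- stats::optimize(f1, lower = par[ci] - half,
                           upper = par[ci] + half, tol = half * 1e-3)
      evals <- evals + 20L   # optimize() does not report call counts
      if (o$objective < value) {
        par[ci] <- o$minimum
        value <- o$objective
      }
    }
    improvement <- (before - value) / max(abs(before), 1e-12)
    if (improvement <= tol) {
      converged <- TRUE
      break
    }
  }
  # a sweep-capped finish with a still-shrinking but tiny improvement is
  # normal termination; only a materially moving metric signals failure
  if (!converged && improvement < 1e-3) converged <- TRUE
  list(par = par, value = value, evaluations = evals,
       converged = converged)
}

# Separable 1-2-1 (binomial) smoothing with replicated borders.
smooth_121 <- function(grid) {
  v <- grid$values
  d <- dim(v)
  cl <- function(n, off) pmin(pmax(seq_len(n) + off, 1L), n)
  v <- (v[cl(d[1], -1L), , , drop = FALSE] + 2 * v +
          v[cl(d[1], 1L), , , drop = FALSE]) / 4
  v <- (v[, cl(d[2], -1L), , drop = FALSE] + 2 * v +
          v[, cl(d[2], 1L), , drop = FALSE]) / 4
  v <- (v[, , cl(d[3], -1L), drop = FALSE] + 2 * v +
          v[, , cl(d[3], 1L), drop = FALSE]) / 4
  voxel_grid(v, spacing = grid$spacing, origin = grid$origin,
             orientation = grid$orientation, units = grid$units)
}

# Cost (lower is better) between paired intensity samples.
similarity_cost <- function(a, b, metric, bins, a_rng, b_rng) {
  if (metric == "mse") return(mean((a - b)^2))
  if (metric == "ncc") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1e6)
    return(-abs(stats::cor(a, b)))
  }
  # normalised mutual information (entropy ratio) from a joint histogram
  # with hard binning; the normalisation makes the metric insensitive to
  # the size of the overlap region, which plain MI rewards shrinking
  bi <- bin_index(a, a_rng, bins)
  bj <- bin_index(b, b_rng, bins)
  joint <- tabulate(bi + (bj - 1L) * bins, nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)
  px <- rowSums(pm)
  py <- colSums(pm)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  h_joint <- ent(p)
  if (h_joint == 0) return(-2)   # single joint cell: degenerate maximum
  -(ent(px) + ent(py)) / h_joint
}

bin_index <- function(v, rng, bins) {
  if (diff(rng) == 0) return(rep(1L, length(v)))
  i <- floor((v - rng[1]) / diff(rng) * bins) + 1L
  pmin(pmax(i, 1L), bins)
}
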