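# Minimal 3D binary morphology. Deliberately array-based and dependency-free:
# the installed image stacks are 2D-oriented, and segmentation only needs
# connected components, hole filling and small ball erosions/dilations.

# Voxel offsets for 6- or 26-connectivity.
connectivity_offsets <- function(connectivity = 26) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

#' Label connected components of a 3D binary array
#'
#' Min-label propagation with path compression; deterministic. Component ids
#' are renumbered 1..k in order of first (lowest linear index) voxel.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer array of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  out <- array(0L, dims)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(out)
  pos <- integer(prod(dims))
  pos[idx] <- seq_len(n)
  coords <- arrayInd(idx, dims)
  offs <- connectivity_offsets(connectivity)
  # neighbour lookup: n x n_offsets matrix of positions within the mask (0 = none)
  nb <- matrix(0L, n, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    ni <- coords[, 1] + offs[o, 1]
    nj <- coords[, 2] + offs[o, 2]
    nk <- coords[, 3] + offs[o, 3]
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
      nk >= 1 & nk <= dims[3]
    lin <- ni[ok] + (nj[ok] - 1) * dims[1] + (nk[ok] - 1) * dims[1] * dims[2]
    nb[ok, o] <- pos[lin]
  }
  labels <- seq_len(n)
  repeat {
    prev <- labels
    for (o in seq_len(ncol(nb))) {
      w <- which(nb[, o] > 0L)
      if (!length(w)) next
      labels[w] <- pmin(labels[w], labels[nb[w, o]])
    }
    # path compression
    repeat {
      l2 <- labels[labels]
      if (identical(l2, labels)) break
      labels <- l2
    }
    if (identical(labels, prev)) break
  }
  # renumber roots 1..k by first occurrence
  roots <- unique(labels)
  remap <- integer(n)
  remap[roots] <- seq_along(roots)
  out[idx] <- remap[labels]
  out
}

# Largest component of a labelled array under the deterministic tie-break:
# voxel count, then max `intensity` within the component, then lowest linear
# index. Returns the component's logical array (all-FALSE if no foreground).
largest_component <- function(labels, intensity = NULL) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (!length(ids)) return(array(FALSE, dim(labels)))
  counts <- vapply(ids, function(i) sum(labels == i), integer(1))
  best <- ids[counts == max(counts)]
  if (length(best) > 1L && !is.null(intensity)) {
    mx <- vapply(best, function(i) max(intensity[labels == i]), numeric(1))
    best <- best[mx == max(mx)]
  }
  if (length(best) > 1L) {
    first <- vapply(best, function(i) which(labels == i)[1], integer(1))
    best <- best[which.min(first)]
  }
  labels == best[1]
}

#' Fill interior holes of a 3D binary mask
#'
#' Background voxels not 6-connected to the array border are interior holes
#' and are set to TRUE.
#'
#' @param mask logical 3D array.
#' @return logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  comp <- label_components(!mask, connectivity = 6)
  dims <- dim(mask)
  border <- unique(c(
    comp[c(1, dims[1]), , ], comp[, c(1, dims[2]), ], comp[, , c(1, dims[3])]))
  border <- setdiff(border, 0L)
  mask | (comp != 0L & !(comp %in% border))
}

# Shift a logical array by an integer voxel offset, padding with `pad`.
shift_array <- function(a, off, pad = FALSE) {
  dims <- dim(a)
  out <- array(pad, dims)
  src <- dst <- vector("list", 3)
  for (d in 1:3) {
    o <- off[d]
    if (o >= 0) {
      dst[[d]] <- seq_len(dims[d] - o) + o
      src[[d]] <- seq_len(dims[d] - o)
    } else {
      dst[[d]] <- seq_len(dims[d] + o)
      src[[d]] <- seq_len(dims[d] + o) - o
    }
    if (!length(src[[d]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Integer voxel offsets inside a closed ball of radius_mm (excluding 0).
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(floor(radius_mm / spacing), 0)
  if (all(r == 0)) return(matrix(numeric(0), 0, 3))
  g <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  g[d2 <= radius_mm^2 + 1e-9 & d2 > 0, , drop = FALSE]
}

#' Erode or dilate a 3D binary mask by a metric ball
#'
#' Erosion keeps voxels whose whole spherical neighbourhood of radius
#' `radius_mm` lies inside the mask (the outside of the array counts as
#' background); dilation adds every voxel within that radius of the mask.
#'
#' @param mask logical 3D array.
#' @param radius_mm ball radius in mm; a radius smaller than one voxel
#'   leaves the mask unchanged.
#' @param spacing voxel spacing triple in mm.
#' @return logical array.
#' @export
erode_ball <- function(mask, radius_mm, spacing) {
  offs <- ball_offsets(radius_mm, spacing)
  out <- mask
  for (o in seq_len(nrow(offs)))
    out <- out & shift_array(mask, offs[o, ], pad = FALSE)
  out
}

#' @rdname erode_ball
#' @export
dilate_ball <- function(mask, radius_mm, spacing) {
  offs <- ball_offsets(radius_mm, spacing)
  out <- mask
  for (o in seq_len(nrow(offs)))
    out <- out | shift_array(mask, offs[o, ], pad = FALSE)
  out
}

# Otsu's threshold on a numeric vector (maximises between-class variance).
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  h <- hist(values, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}
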