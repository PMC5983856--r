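# Internal 3-D grid helpers shared by the phantom and segmentation code.
# All arrays follow (slice, row, col) axis order, 1-based indices.

# Run code with a temporarily seeded RNG, restoring global state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift an array by (ds, dr, dc), filling vacated voxels with `fill`.
shift3d <- function(a, ds, dr, dc, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- list(seq_len(d[1]) - ds, seq_len(d[2]) - dr, seq_len(d[3]) - dc)
  keep <- lapply(seq_len(3), function(i) src[[i]] >= 1L & src[[i]] <= d[i])
  out[keep[[1]], keep[[2]], keep[[3]]] <-
    a[src[[1]][keep[[1]]], src[[2]][keep[[2]]], src[[3]][keep[[3]]]]
  out
}

neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(ds = -1:1, dr = -1:1, dc = -1:1)
  g <- g[!(g$ds == 0 & g$dr == 0 & g$dc == 0), ]
  if (connectivity == 6L)
    g <- g[abs(g$ds) + abs(g$dr) + abs(g$dc) == 1L, ]
  as.matrix(g)
}

# One binary dilation step with the given connectivity.
dilate3d <- function(mask, connectivity = 6L, steps = 1L) {
  off <- neighbor_offsets(connectivity)
  for (s in seq_len(steps)) {
    acc <- mask
    for (i in seq_len(nrow(off)))
      acc <- acc | shift3d(mask, off[i, 1], off[i, 2], off[i, 3])
    mask <- acc
  }
  mask
}

# Approximate Euclidean distance (mm) from every voxel to the seed set,
# by band-limited 26-neighbour chamfer propagation.  Distances beyond
# `max_dist` are left at Inf; adequate for narrow-band surface queries.
chamfer_distance <- function(seed_set, spacing, max_dist) {
  off <- neighbor_offsets(26L)
  w <- sqrt((off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
              (off[, 3] * spacing[3])^2)
  d <- array(Inf, dim = dim(seed_set))
  d[seed_set] <- 0
  n_pass <- ceiling(max_dist / min(spacing)) + 1L
  for (p in seq_len(n_pass)) {
    changed <- FALSE
    for (i in seq_len(nrow(off))) {
      cand <- shift3d(d, off[i, 1], off[i, 2], off[i, 3], fill = Inf) + w[i]
      upd <- cand < d
      if (any(upd)) {
        d[upd] <- cand[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

# Separable Gaussian smoothing of a 3-D array, sigma given in voxels per
# axis; replicate padding at the edges.
gaussian_smooth3d <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    a <- convolve_axis(a, k, axis)
  }
  a
}

convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  half <- (length(k) - 1L) / 2L
  # replicate-pad the filtered axis
  mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
              m[rep(nrow(m), half), , drop = FALSE])
  out <- matrix(0, nrow = nrow(m), ncol = ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[(j - 1L) + seq_len(nrow(m)), , drop = FALSE]
  ap <- array(out, dim = d[perm])
  aperm(ap, order(perm))
}

# Connected component of `mask` containing the seed voxel, by frontier
# expansion.  Returns a logical array; empty if seed is outside the mask.
connected_component <- function(mask, seed_idx, connectivity = 26L) {
  comp <- array(FALSE, dim = dim(mask))
  if (!mask[seed_idx[1], seed_idx[2], seed_idx[3]]) return(comp)
  off <- neighbor_offsets(connectivity)
  comp[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  frontier <- comp
  repeat {
    grown <- array(FALSE, dim = dim(mask))
    for (i in seq_len(nrow(off)))
      grown <- grown | shift3d(frontier, off[i, 1], off[i, 2], off[i, 3])
    frontier <- grown & mask & !comp
    if (!any(frontier)) break
    comp <- comp | frontier
  }
  comp
}

# Largest connected component (26-connectivity) that intersects `anchor`;
# used to keep simulated observer masks connected.
component_containing <- function(mask, anchor, connectivity = 26L) {
  if (!any(mask & anchor)) return(array(FALSE, dim = dim(mask)))
  idx <- which(mask & anchor, arr.ind = TRUE)[1, ]
  connected_component(mask, idx, connectivity)
}
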