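# Independent voxel-space oracles used throughout: membership is decided
# by explicit Euclidean distance computations over voxel center
# coordinates, never by the package's array-shift machinery.

# All voxel centers of a grid, in angstrom, with linear indices.
grid_centers <- function(grid) {
  idx <- as.matrix(expand.grid(i = seq_len(grid$dim[1L]),
                               j = seq_len(grid$dim[2L]),
                               k = seq_len(grid$dim[3L])))
  xyz <- sweep((idx - 1L) * grid$spacing, 2L, grid$origin, "+")
  list(idx = idx, xyz = xyz,
       lin = idx[, 1L] + grid$dim[1L] * (idx[, 2L] - 1L) +
         grid$dim[1L] * grid$dim[2L] * (idx[, 3L] - 1L))
}

# min distance from each row of a to any row of b (small sets)
min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  sqrt(pmax(apply(d2, 1L, min), 0))
}

oracle_occupancy <- function(grid, atoms) {
  g <- grid_centers(grid)
  occ <- rep(FALSE, nrow(g$xyz))
  for (k in seq_len(nrow(atoms))) {
    d <- sqrt(rowSums(sweep(g$xyz, 2L,
                            unlist(atoms[k, c("x", "y", "z")]), "-")^2))
    occ <- occ | (d <= atoms$vdw[k] + 1e-12)
  }
  occ
}

oracle_dilate <- function(occ_vec, grid, radius) {
  g <- grid_centers(grid)
  src <- g$xyz[occ_vec, , drop = FALSE]
  if (nrow(src) == 0L) return(rep(FALSE, length(occ_vec)))
  min_dist(g$xyz, src) <= radius + 1e-12
}

oracle_erode <- function(occ_vec, grid, radius) {
  g <- grid_centers(grid)
  out <- rep(FALSE, length(occ_vec))
  rows <- which(occ_vec)
  if (length(rows) == 0L) return(out)
  bg <- g$xyz[!occ_vec, , drop = FALSE]
  keep <- rep(TRUE, length(rows))
  if (nrow(bg) > 0L)
    keep <- min_dist(g$xyz[rows, , drop = FALSE], bg) > radius + 1e-12
  # the nearest virtual background voxel outside the lattice sits one
  # spacing beyond the boundary plane
  lo <- grid$origin
  hi <- grid$origin + (grid$dim - 1L) * grid$spacing
  xyz <- g$xyz[rows, , drop = FALSE]
  edge <- pmin(xyz[, 1L] - lo[1L], xyz[, 2L] - lo[2L],
               xyz[, 3L] - lo[3L], hi[1L] - xyz[, 1L],
               hi[2L] - xyz[, 2L], hi[3L] - xyz[, 3L])
  keep <- keep & (edge + grid$spacing > radius + 1e-12)
  out[rows[keep]] <- TRUE
  out
}

random_grid <- function(n = 8L, p = 0.4) {
  occ <- array(stats::runif(n^3) < p, dim = c(n, n, n))
  structure(list(origin = c(0, 0, 0), spacing = 1.0,
                 dim = c(n, n, n), occ = occ, padding = NA_real_),
            class = "voxel_grid")
}

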