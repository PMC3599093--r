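# Grid-based 3D mathematical morphology.
#
# The antigen is discretized as a binary characteristic function f over a
# voxel lattice: the object X = {v : f(v) = 1}, background X^c = {v :
# f(v) = 0}. Dilation by a small digital ball B1 followed by erosion of
# the dilated set by a strictly larger ball B2 yields, via set difference,
# a surface shell from which per-atom exposure (surface rates) is read.

#' Digital ball structuring element
#'
#' The set of integer offsets `d` with `||d|| * spacing <= radius`.
#' Contains the origin and is centrally symmetric, so the element equals
#' its own reflection.
#'
#' @param radius Ball radius in angstrom (`>= 0`).
#' @param spacing Grid spacing in angstrom (`> 0`).
#' @return A `structuring_element`: list with `radius`, `spacing` and an
#'   integer offset matrix `offsets` (n x 3).
#' @export
ball_element <- function(radius, spacing) {
  stopifnot(radius >= 0, spacing > 0)
  m <- floor(radius / spacing)
  g <- seq.int(-m, m)
  d <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- sqrt(rowSums(d^2)) * spacing <= radius + 1e-12
  structure(list(radius = radius, spacing = spacing,
                 offsets = d[keep, , drop = FALSE]),
            class = "structuring_element")
}

.new_grid <- function(occ, origin, spacing, padding = NA_real_) {
  structure(list(origin = origin, spacing = spacing, dim = dim(occ),
                 occ = occ, padding = padding),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s @ %.2f A, %d occupied of %d voxels\n",
              paste(x$dim, collapse = "x"), x$spacing, sum(x$occ),
              prod(x$dim)))
  invisible(x)
}

#' Voxelize a structure
#'
#' A voxel is occupied iff its center lies within some heavy atom's van
#' der Waals radius, so the occupied set is the grid sampling of the union
#' of atomic balls. The grid encloses all heavy atoms plus `padding` on
#' every side, which must be large enough for the subsequent dilation.
#'
#' @param structure An `antigen_structure` with vdw radii assigned.
#' @param spacing Isotropic grid spacing in angstrom.
#' @param padding Margin in angstrom added around the atom bounding box.
#' @return A `voxel_grid` (`origin`, `spacing`, `dim`, logical array
#'   `occ`).
#' @export
voxelize <- function(structure, spacing = 1.0, padding = 8.0) {
  if (spacing <= 0) stop("invalid parameter: spacing must be > 0")
  at <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  if (nrow(at) == 0L) stop("structure has no heavy atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  lo <- apply(xyz, 2L, min) - padding
  hi <- apply(xyz, 2L, max) + padding
  dm <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  occ <- array(FALSE, dim = dm)
  for (k in seq_len(nrow(at))) {
    occ <- .paint_ball(occ, lo, spacing, xyz[k, ], at$vdw[k])
  }
  .new_grid(occ, lo, spacing, padding)
}

# Mark voxels whose centers are within `r` of `center`.
.paint_ball <- function(occ, origin, spacing, center, r) {
  dm <- dim(occ)
  ctr <- (center - origin) / spacing        # 0-based grid coords
  m <- r / spacing
  rng <- lapply(1:3, function(a) {
    lo <- max(0L, floor(ctr[a] - m))
    hi <- min(dm[a] - 1L, ceiling(ctr[a] + m))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0L)) return(occ)
  dx2 <- (rng[[1L]] - ctr[1L])^2
  dy2 <- (rng[[2L]] - ctr[2L])^2
  dz2 <- (rng[[3L]] - ctr[3L])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  inside <- d2 <= m^2 + 1e-12
  sub <- occ[rng[[1L]] + 1L, rng[[2L]] + 1L, rng[[3L]] + 1L, drop = FALSE]
  occ[rng[[1L]] + 1L, rng[[2L]] + 1L, rng[[3L]] + 1L] <- sub | inside
  occ
}

# Translate a logical array by integer offset d, zero-filling.
.shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dim = dm)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) {
      if (d[k] >= dm[k]) return(out)
      dst[[k]] <- (1L + d[k]):dm[k]
      src[[k]] <- 1L:(dm[k] - d[k])
    } else {
      if (-d[k] >= dm[k]) return(out)
      dst[[k]] <- 1L:(dm[k] + d[k])
      src[[k]] <- (1L - d[k]):dm[k]
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <-
    a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

.check_element <- function(grid, element) {
  if (abs(grid$spacing - element$spacing) > 1e-9)
    stop("structuring element spacing does not match grid spacing")
  if (!is.na(grid$padding) && element$radius > grid$padding + 1e-9)
    stop("padding insufficient for structuring element of radius ",
         element$radius)
}

#' Morphological dilation
#'
#' Output voxel `v` is occupied iff the (symmetric) element translated to
#' `v` intersects the object; equivalently the union of translates of the
#' object by the element's offsets.
#'
#' @param grid A `voxel_grid`.
#' @param element A `structuring_element` with matching spacing.
#' @return Dilated `voxel_grid`.
#' @export
dilate <- function(grid, element) {
  .check_element(grid, element)
  off <- element$offsets
  out <- array(FALSE, dim = grid$dim)
  for (k in seq_len(nrow(off))) out <- out | .shift_array(grid$occ, off[k, ])
  .new_grid(out, grid$origin, grid$spacing, grid$padding)
}

#' Morphological erosion
#'
#' Output voxel `v` is occupied iff every translate `v + d` over the
#' element's offsets is occupied in the input (voxels outside the grid
#' count as background). Implemented through the duality
#' `erode(X, B) = complement(dilate(complement(X), B))` for symmetric
#' elements, with explicit background outside the lattice.
#'
#' @inheritParams dilate
#' @return Eroded `voxel_grid`.
#' @export
erode <- function(grid, element) {
  .check_element(grid, element)
  off <- element$offsets
  out <- array(TRUE, dim = grid$dim)
  for (k in seq_len(nrow(off))) {
    out <- out & .shift_array(grid$occ, -off[k, ])
  }
  .new_grid(out, grid$origin, grid$spacing, grid$padding)
}

#' Surface shell by dilation--erosion difference
#'
#' Computes `XD = dilate(X, B1)`, `XE = erode(XD, B2)` with `B2` strictly
#' larger than `B1`, and returns the set difference `XD \ XE`: a shell of
#' voxels hugging the solvent-exposed boundary of the structure.
#'
#' @param structure An `antigen_structure`.
#' @param spacing Grid spacing in angstrom.
#' @param b1_radius Radius of the fundamental ball `B1` (default 1.5).
#' @param b2_radius Radius of the larger ball `B2`; default
#'   `b1_radius + spacing`, the smallest strictly-larger digital ball at
#'   the working spacing. This keeps the shell about one voxel deeper
#'   than the dilated boundary, so AR grades exposure smoothly instead of
#'   saturating at 1 for every exposed atom.
#' @param padding Grid margin; default `b2_radius` + max vdw radius +
#'   `2 * spacing` so dilation never clips.
#' @return List with voxel grids `x` (occupancy), `xd`, `xe`, `shell`
#'   (class `surface_shell`).
#' @export
surface_shell <- function(structure, spacing = 1.0, b1_radius = 1.5,
                          b2_radius = b1_radius + spacing,
                          padding = NULL) {
  if (b2_radius <= b1_radius)
    stop("invalid parameter: b2_radius must exceed b1_radius")
  heavy <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  if (is.null(padding))
    padding <- b2_radius + max(heavy$vdw, 1.7) + 2 * spacing
  x <- voxelize(structure, spacing = spacing, padding = padding)
  b1 <- ball_element(b1_radius, spacing)
  b2 <- ball_element(b2_radius, spacing)
  xd <- dilate(x, b1)
  xe <- erode(xd, b2)
  shell <- .new_grid(xd$occ & !xe$occ, x$origin, x$spacing, x$padding)
  structure(list(x = x, xd = xd, xe = xe, shell = shell,
                 spacing = spacing, b1_radius = b1_radius,
                 b2_radius = b2_radius),
            class = "surface_shell")
}

# Linear indices (1-based) of voxels within `r` of `center`.
.ball_voxel_index <- function(grid, center, r) {
  dm <- grid$dim
  ctr <- (center - grid$origin) / grid$spacing
  m <- r / grid$spacing
  rng <- lapply(1:3, function(a) {
    lo <- max(0L, floor(ctr[a] - m))
    hi <- min(dm[a] - 1L, ceiling(ctr[a] + m))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0L)) return(integer(0))
  dx2 <- (rng[[1L]] - ctr[1L])^2
  dy2 <- (rng[[2L]] - ctr[2L])^2
  dz2 <- (rng[[3L]] - ctr[3L])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  idx <- which(d2 <= m^2 + 1e-12, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(integer(0))
  i <- rng[[1L]][idx[, 1L]] + 1L
  j <- rng[[2L]][idx[, 2L]] + 1L
  k <- rng[[3L]][idx[, 3L]] + 1L
  i + dm[1L] * (j - 1L) + dm[1L] * dm[2L] * (k - 1L)
}

#' Per-atom surface rate AR
#'
#' An atom's own voxels are the occupied voxels within its van der Waals
#' radius; its surface rate AR is the fraction of those lying in the
#' morphological shell. Atoms too small for the grid to resolve (no own
#' voxels) get AR = 0 with a warning.
#'
#' @param atom One-row atom data frame (needs `x`, `y`, `z`, `vdw`).
#' @param shell Shell `voxel_grid` (from [surface_shell()]).
#' @param occupied Occupancy `voxel_grid` of the same geometry.
#' @return AR in `[0, 1]`.
#' @export
atom_surface_rate <- function(atom, shell, occupied) {
  stopifnot(all(abs(shell$origin - occupied$origin) < 1e-9),
            abs(shell$spacing - occupied$spacing) < 1e-9)
  idx <- .ball_voxel_index(occupied, c(atom$x, atom$y, atom$z), atom$vdw)
  idx <- idx[occupied$occ[idx]]
  if (length(idx) == 0L) {
    warning("atom has no resolved voxels at this spacing; AR set to 0")
    return(0)
  }
  sum(shell$occ[idx]) / length(idx)
}

#' Surface rates for all heavy atoms of a structure
#'
#' Convenience wrapper: builds the shell once and evaluates
#' [atom_surface_rate()] for every heavy atom.
#'
#' @inheritParams surface_shell
#' @return List with the `surface_shell` object and numeric `ar`, one
#'   value per atom row of the structure (NA for hydrogens).
#' @export
surface_rates <- function(structure, spacing = 1.0, b1_radius = 1.5,
                          b2_radius = b1_radius + spacing) {
  sh <- surface_shell(structure, spacing, b1_radius, b2_radius)
  at <- structure$atoms
  ar <- rep(NA_real_, nrow(at))
  heavy <- which(at$is_heavy)
  shell_occ <- sh$shell$occ
  x_occ <- sh$x$occ
  for (k in heavy) {
    idx <- .ball_voxel_index(sh$x, c(at$x[k], at$y[k], at$z[k]), at$vdw[k])
    idx <- idx[x_occ[idx]]
    ar[k] <- if (length(idx) == 0L) 0 else sum(shell_occ[idx]) / length(idx)
  }
  list(shell = sh, ar = ar)
}

#' Write shell voxels as PDB pseudo-atoms (debug aid)
#'
#' @param shell A `surface_shell` or shell `voxel_grid`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_shell_pdb <- function(shell, path) {
  g <- if (inherits(shell, "surface_shell")) shell$shell else shell
  idx <- which(g$occ, arr.ind = TRUE)
  xyz <- sweep((idx - 1L) * g$spacing, 2L, g$origin, "+")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(xyz))) {
    writeLines(sprintf(
      "HETATM%5d  X   SHL X%4d    %8.3f%8.3f%8.3f  1.00  0.00           X",
      i %% 100000L, i %% 10000L, xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]), con)
  }
  writeLines("END", con)
  invisible(path)
}
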