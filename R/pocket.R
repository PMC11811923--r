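# ---------------------------------------------------------------------------
# Grid-based cavity volume: probe-excluded voxels flood-filled from a seed,
# with a larger probe defining the bulk solvent region.
# ---------------------------------------------------------------------------

# van der Waals radii (A), Bondi-style standard set; fallback 1.70
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, D = 1.20,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Specify the cavity-detection grid
#'
#' @param seed_point 3-vector (Angstrom) inside the cavity of interest,
#'   outside every atom's van der Waals sphere.
#' @param spacing Voxel edge (Angstrom); must not exceed `small_probe`.
#' @param small_probe Solvent probe radius (Angstrom) added to atom radii
#'   when excluding voxels.
#' @param large_probe Bulk probe radius; the region a probe this large can
#'   reach from outside the structure is treated as bulk solvent, not
#'   cavity.
#' @param padding Extra margin around the atom bounding box (Angstrom).
#' @return A `GridSpec`.
#' @export
grid_spec <- function(seed_point, spacing = 0.5, small_probe = 1.4,
                      large_probe = 3.4, padding = 4) {
  seed_point <- vec3(seed_point)
  if (!(spacing > 0 && spacing <= small_probe)) {
    stop("need 0 < spacing <= small_probe", call. = FALSE)
  }
  if (!(small_probe < large_probe)) stop("need small_probe < large_probe", call. = FALSE)
  structure(list(seed_point = seed_point, spacing = spacing,
                 small_probe = small_probe, large_probe = large_probe,
                 padding = padding),
            class = "GridSpec")
}

# flood fill (6-connectivity) over `free` from linear start indices
flood_fill3 <- function(free, dims, start) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  nxy <- nx * ny
  visited <- logical(length(free))
  frontier <- start[free[start] & !visited[start]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    idx0 <- frontier - 1L
    ix <- idx0 %% nx
    iz <- idx0 %/% nxy
    iy <- (idx0 %/% nx) %% ny
    cand <- c(frontier[ix > 0L] - 1L,       frontier[ix < nx - 1L] + 1L,
              frontier[iy > 0L] - nx,       frontier[iy < ny - 1L] + nx,
              frontier[iz > 0L] - nxy,      frontier[iz < nz - 1L] + nxy)
    cand <- unique(cand)
    cand <- cand[free[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# mark voxels within (vdw + probe) of any atom; returns logical vector
occlude_grid <- function(gx, gy, gz, xyz, radii, probe) {
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  occ <- logical(nx * ny * nz)
  sp <- gx[2L] - gx[1L]
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a] + probe
    cx <- xyz[a, 1L]; cy <- xyz[a, 2L]; cz <- xyz[a, 3L]
    ix <- which(abs(gx - cx) <= r)
    iy <- which(abs(gy - cy) <= r)
    iz <- which(abs(gz - cz) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - cx)^2
    dy2 <- (gy[iy] - cy)^2
    dz2 <- (gz[iz] - cz)^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r * r
    if (!any(sub)) next
    lin <- which(sub, arr.ind = TRUE)
    occ[ix[lin[, 1L]] + (iy[lin[, 2L]] - 1L) * nx +
          (iz[lin[, 3L]] - 1L) * nx * ny] <- TRUE
  }
  occ
}

#' Estimate the volume of an enclosed cavity on a voxel grid
#'
#' A voxel belongs to the cavity when it is (a) outside every atom sphere
#' inflated by the small (solvent) probe, (b) flood-fill connected to the
#' seed point through such voxels, and (c) not part of the bulk solvent,
#' defined as the free space a large probe can reach from the grid
#' boundary. If the seed's component touches bulk solvent the volume is
#' still returned, flagged `open = TRUE`.
#'
#' @param s A `Structure`.
#' @param g A `GridSpec`.
#' @param sel Optional `Selection` restricting the atoms considered.
#' @return List: `volume` (Angstrom^3), `n_voxels`, `voxels` (n x 3 matrix
#'   of cavity voxel centres), `open` flag, `spec` (the grid used).
#' @export
cavity_volume <- function(s, g, sel = NULL) {
  stopifnot(inherits(g, "GridSpec"))
  idx <- select_atoms(s, sel)
  if (!length(idx)) stop("selection matches no atoms", call. = FALSE)
  xyz <- coords(s, idx)
  radii <- vdw_radius(s$atoms$element[idx])

  seed <- g$seed_point
  d_seed <- sqrt(rowSums(sweep(xyz, 2L, seed)^2))
  if (any(d_seed < radii)) {
    stop("seed point lies inside an atom's van der Waals sphere", call. = FALSE)
  }

  sp <- g$spacing
  lo <- apply(xyz, 2L, min) - g$padding
  hi <- apply(xyz, 2L, max) + g$padding
  lo <- pmin(lo, seed - 2 * sp); hi <- pmax(hi, seed + 2 * sp)
  # lattice anchored at the seed point, so voxel alignment does not depend
  # on the extent of the structure
  axis_grid <- function(k) {
    seed[k] + seq(floor((lo[k] - seed[k]) / sp), ceiling((hi[k] - seed[k]) / sp)) * sp
  }
  gx <- axis_grid(1L)
  gy <- axis_grid(2L)
  gz <- axis_grid(3L)
  dims <- c(length(gx), length(gy), length(gz))
  nvox <- prod(dims)

  occ_small <- occlude_grid(gx, gy, gz, xyz, radii, g$small_probe)
  occ_large <- occlude_grid(gx, gy, gz, xyz, radii, g$large_probe)
  free_small <- !occ_small
  free_large <- !occ_large

  # bulk: large-probe-accessible space connected to the grid boundary
  bnd <- boundary_indices(dims)
  bulk_core <- flood_fill3(free_large, dims, bnd)
  # everything the solvent probe reaches from bulk
  outside <- flood_fill3(free_small, dims, which(bulk_core))

  seed_idx <- grid_index(seed, gx, gy, gz, dims)
  if (is.na(seed_idx) || !free_small[seed_idx]) {
    stop("seed point is occluded at the small-probe surface: not in open cavity space",
         call. = FALSE)
  }
  comp <- flood_fill3(free_small, dims, seed_idx)
  open <- any(comp & bulk_core)
  cav <- comp & !bulk_core
  n <- sum(cav)
  lin <- which(cav) - 1L
  vox <- cbind(gx[(lin %% dims[1L]) + 1L],
               gy[((lin %/% dims[1L]) %% dims[2L]) + 1L],
               gz[(lin %/% (dims[1L] * dims[2L])) + 1L])
  colnames(vox) <- c("x", "y", "z")
  list(volume = n * sp^3, n_voxels = n, voxels = vox, open = open, spec = g)
}

boundary_indices <- function(dims) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  ar <- array(FALSE, dims)
  ar[c(1L, nx), , ] <- TRUE
  ar[, c(1L, ny), ] <- TRUE
  ar[, , c(1L, nz)] <- TRUE
  which(ar)
}

grid_index <- function(p, gx, gy, gz, dims) {
  ix <- which.min(abs(gx - p[1L]))
  iy <- which.min(abs(gy - p[2L]))
  iz <- which.min(abs(gz - p[3L]))
  if (!length(ix) || !length(iy) || !length(iz)) return(NA_integer_)
  ix + (iy - 1L) * dims[1L] + (iz - 1L) * dims[1L] * dims[2L]
}
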