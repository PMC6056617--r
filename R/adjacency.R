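#' Neighbor offsets for a named 3D connectivity
#'
#' @param connectivity one of 6 (faces), 18 (faces+edges), 26 (full 3x3x3
#'   neighborhood minus centre).
#' @return integer matrix, one row per offset, columns dx/dy/dz. The set is
#'   symmetric and excludes the zero offset.
#' @export
adjacency_offsets <- function(connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stopf("connectivity must be 6, 18 or 26, got %d", connectivity)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nn <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = nn == 1L,
                 "18" = nn >= 1L & nn <= 2L,
                 "26" = nn >= 1L)
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Neighbor offsets within a Euclidean radius
#'
#' Enumerates every nonzero integer voxel offset whose centre-to-centre
#' distance in mm is at most `radius_mm`. This is how a cluster "connection
#' radius" (e.g. the 5 mm AlphaSim setting) maps onto a discrete
#' neighborhood: with 3 mm isotropic voxels, r = 5 mm keeps the 6 face
#' neighbors (3 mm) and 12 edge neighbors (~4.24 mm) but not the 8 corner
#' neighbors (~5.20 mm) - 18 offsets.
#'
#' @param voxel_size_mm length-3 voxel dimensions in mm.
#' @param radius_mm connection radius in mm.
#' @return integer offset matrix as in [adjacency_offsets()].
#' @export
adjacency_from_radius <- function(voxel_size_mm, radius_mm) {
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (radius_mm < min(voxel_size_mm))
    stopf("radius %g mm is below the smallest face-neighbor distance %g mm: no clusters possible",
          radius_mm, min(voxel_size_mm))
  r_vox <- ceiling(radius_mm / voxel_size_mm)
  g <- as.matrix(expand.grid(dx = -r_vox[1]:r_vox[1],
                             dy = -r_vox[2]:r_vox[2],
                             dz = -r_vox[3]:r_vox[3]))
  d <- sqrt((g[, 1] * voxel_size_mm[1])^2 + (g[, 2] * voxel_size_mm[2])^2 +
              (g[, 3] * voxel_size_mm[3])^2)
  out <- g[d <= radius_mm & d > 0, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

## CSR neighbor graph over the in-mask voxels: for mask voxel i (in mask
## ordering), its in-mask neighbors under `offsets`. Used by the growing
## algorithm and by connected-component labeling.
mask_neighbor_graph <- function(mask, offsets) {
  dimm <- dim(mask)
  idx <- which(mask)                       # linear indices of mask voxels
  n <- length(idx)
  rank <- integer(prod(dimm)); rank[idx] <- seq_len(n)
  co <- linear_to_coord(idx, dimm)
  from <- vector("list", nrow(offsets)); to <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    sh <- cbind(co[, 1] + offsets[k, 1], co[, 2] + offsets[k, 2], co[, 3] + offsets[k, 3])
    ok <- sh[, 1] >= 1L & sh[, 1] <= dimm[1] & sh[, 2] >= 1L & sh[, 2] <= dimm[2] &
      sh[, 3] >= 1L & sh[, 3] <= dimm[3]
    tgt <- integer(n)
    tgt[ok] <- rank[coord_to_linear(sh[ok, , drop = FALSE], dimm)]
    keep <- tgt > 0L
    from[[k]] <- which(keep); to[[k]] <- tgt[keep]
  }
  from <- unlist(from); to <- unlist(to)
  o <- order(from)
  from <- from[o]; to <- to[o]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(n = n, idx = idx, coords = co, ptr = as.integer(ptr), nbr = as.integer(to))
}
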