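# World <-> voxel coordinate transforms. Voxel indices are 0-based
# throughout the public interface (the NIfTI convention); world coordinates
# are RAS millimetres as encoded in the affine.

roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map a world coordinate to the containing voxel
#'
#' Applies the inverse affine and rounds each continuous voxel coordinate to
#' the nearest integer, halves away from zero. The composition
#' `voxelToWorld(worldToVoxel(p))` moves a point by at most half a voxel
#' diagonal.
#'
#' @param grid an [ImageGrid-class].
#' @param point numeric(3) world coordinate in mm, or an n x 3 matrix of
#'   points.
#' @return Integer 0-based voxel indices (vector or n x 3 matrix).
#'   Errors if any point falls outside the grid.
#' @export
worldToVoxel <- function(grid, point) {
  single <- is.null(dim(point))
  pts <- if (single) matrix(point, nrow = 1) else as.matrix(point)
  stopifnot(ncol(pts) == 3L)
  inv <- solve(grid@affine)
  v <- cbind(pts, 1) %*% t(inv)
  idx <- roundHalfAway(v[, 1:3, drop = FALSE])
  bad <- idx < 0 | idx >= matrix(grid@dim, nrow(idx), 3, byrow = TRUE)
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)[1]
    stop(sprintf("world point (%s) maps outside the grid (voxel %s)",
                 paste(signif(pts[i, ], 6), collapse = ", "),
                 paste(idx[i, ], collapse = ", ")))
  }
  storage.mode(idx) <- "integer"
  if (single) idx[1, ] else idx
}

#' Map 0-based voxel indices to world coordinates (voxel centres)
#'
#' @param grid an [ImageGrid-class].
#' @param voxel integer(3) 0-based voxel index, or an n x 3 matrix.
#' @return World mm coordinates (vector or n x 3 matrix).
#' @export
voxelToWorld <- function(grid, voxel) {
  single <- is.null(dim(voxel))
  v <- if (single) matrix(voxel, nrow = 1) else as.matrix(voxel)
  w <- cbind(v, 1) %*% t(grid@affine)
  w <- w[, 1:3, drop = FALSE]
  if (single) w[1, ] else w
}

# 1-based linear index <-> 0-based (i,j,k) triplets, column-major
linearToVoxel <- function(grid, idx) {
  d <- grid@dim
  idx0 <- idx - 1L
  cbind(idx0 %% d[1],
        (idx0 %/% d[1]) %% d[2],
        idx0 %/% (d[1] * d[2]))
}

voxelToLinear <- function(grid, ijk) {
  d <- grid@dim
  ijk <- if (is.null(dim(ijk))) matrix(ijk, nrow = 1) else ijk
  as.integer(1L + ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3]))
}
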