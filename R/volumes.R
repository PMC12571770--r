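# NIfTI I/O, sphere ROIs and resampling.

gridFromNifti <- function(image) {
  aff <- unname(structure(RNifti::xform(image), imagedim = NULL,
                          code = NULL))
  imageGrid(dim(image)[1:3], affine = matrix(as.numeric(aff), 4, 4))
}

#' Read a 3-D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [VolumeMap-class], or a
#' [VolumeMask-class] when the stored values are all 0/1 (or when
#' `as = "mask"`). The returned grid reproduces the file's affine and the
#' values are the stored data promoted to double.
#'
#' @param path path to a NIfTI-1 file.
#' @param as `"auto"` (mask when the payload is binary), `"map"` or
#'   `"mask"`.
#' @param label label attached when a mask is returned (defaults to the
#'   file name).
#' @return A [VolumeMap-class] or [VolumeMask-class].
#' @export
readVolume <- function(path, as = c("auto", "map", "mask"), label = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L)
    stop(sprintf("expected a 3-D volume, got %d axes in %s", nd, path))
  grid <- gridFromNifti(img)
  vals <- array(as.double(img), dim = grid@dim)
  if (!all(is.finite(vals) | is.na(vals)))
    stop("volume contains non-finite values: ", path)
  binary <- all(vals %in% c(0, 1))
  if (as == "mask" || (as == "auto" && binary)) {
    if (!binary) stop("cannot read non-binary volume as a mask: ", path)
    if (is.null(label)) label <- sub("\\.nii(\\.gz)?$", "", basename(path))
    volumeMask(grid, vals != 0, label = label)
  } else {
    volumeMap(grid, vals)
  }
}

#' Write a volumetric object as NIfTI-1
#'
#' Masks and binarized maps are written as 0/1; undefined voxels of a map
#' are written as NaN. The grid affine is stored in both sform and qform.
#'
#' @param x a [VolumeMap-class], [VolumeMask-class], [BinarizedMap-class]
#'   or [GroupTMap-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  grid <- imageGridOf(x)
  vals <- switch(class(x),
    VolumeMask = ,
    BinarizedMap = array(as.double(x@values), dim = grid@dim),
    GroupTMap = { v <- x@t; v[!x@valid] <- NaN; v },
    VolumeMap = { v <- x@values; v[!x@valid] <- NaN; v },
    stop("cannot write objects of class ", class(x)))
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- gridSpacing(grid)
  img <- RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Spherical seed ROI around a world coordinate
#'
#' Builds the mask of voxels whose centre lies within `radius` mm of the
#' centre of the voxel containing `centerWorld` (inclusive). This is the
#' construction used for stimulation-site seeds (3-mm radius spheres at
#' reported coordinates).
#'
#' @param grid an [ImageGrid-class].
#' @param centerWorld numeric(3) world mm coordinate; must fall inside the
#'   grid.
#' @param radius sphere radius in mm, `>= 0`. Radius 0 yields exactly the
#'   containing voxel.
#' @param label mask label.
#' @return A [VolumeMask-class] with at least one voxel.
#' @export
sphereROI <- function(grid, centerWorld, radius, label = "sphere") {
  stopifnot(radius >= 0)
  cv <- worldToVoxel(grid, centerWorld)   # errors when outside the grid
  cw <- voxelToWorld(grid, cv)
  # candidate bounding box in voxel units
  sp <- gridSpacing(grid)
  half <- ceiling(radius / sp) + 1L
  rng <- lapply(1:3, function(a) {
    seq(max(0L, cv[a] - half[a]), min(grid@dim[a] - 1L, cv[a] + half[a]))
  })
  cand <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  w <- voxelToWorld(grid, cand)
  d2 <- rowSums((w - matrix(cw, nrow(w), 3, byrow = TRUE))^2)
  keep <- cand[d2 <= radius^2 + 1e-9, , drop = FALSE]
  vals <- array(FALSE, dim = grid@dim)
  vals[voxelToLinear(grid, keep)] <- TRUE
  volumeMask(grid, vals, label = label)
}

#' Resample a mask to another grid (nearest neighbour)
#'
#' Each target voxel centre is mapped through both affines into the source
#' grid and takes the nearest source voxel's value. Resampling a mask to
#' its own grid is the identity. Binarity is preserved by construction.
#'
#' @param mask a [VolumeMask-class].
#' @param target the destination [ImageGrid-class] (same world space).
#' @return A [VolumeMask-class] on `target`. Errors when a nonempty source
#'   mask resamples to zero voxels (non-overlapping fields of view).
#' @export
resampleMask <- function(mask, target) {
  if (sameGrid(mask@grid, target)) return(mask)
  src <- mask@grid
  tIdx <- linearToVoxel(target, seq_len(prod(target@dim)))
  w <- voxelToWorld(target, tIdx)
  u <- cbind(w, 1) %*% t(solve(src@affine))
  sIdx <- roundHalfAway(u[, 1:3, drop = FALSE])
  inside <- sIdx[, 1] >= 0 & sIdx[, 1] < src@dim[1] &
            sIdx[, 2] >= 0 & sIdx[, 2] < src@dim[2] &
            sIdx[, 3] >= 0 & sIdx[, 3] < src@dim[3]
  vals <- array(FALSE, dim = target@dim)
  if (any(inside))
    vals[which(inside)] <- mask@values[voxelToLinear(src, sIdx[inside, ,
                                                               drop = FALSE])]
  if (sum(mask@values) > 0L && sum(vals) == 0L)
    stop(sprintf("mask '%s' resampled to 0 voxels: grids do not overlap",
                 mask@label))
  volumeMask(target, vals, label = mask@label)
}

#' Resample a continuous map to another grid (trilinear)
#'
#' Target voxel centres are interpolated trilinearly in the source volume.
#' Voxels falling outside the source field of view, or whose interpolation
#' stencil touches an undefined source voxel, are marked undefined.
#'
#' @param map a [VolumeMap-class].
#' @param target the destination [ImageGrid-class].
#' @return A [VolumeMap-class] on `target`.
#' @export
resampleMap <- function(map, target) {
  if (sameGrid(map@grid, target)) return(map)
  src <- map@grid
  tIdx <- linearToVoxel(target, seq_len(prod(target@dim)))
  w <- voxelToWorld(target, tIdx)
  u <- (cbind(w, 1) %*% t(solve(src@affine)))[, 1:3, drop = FALSE]
  lo <- floor(u)
  fr <- u - lo
  vals <- rep(0, nrow(u))
  wsum <- rep(0, nrow(u))
  bad <- rep(FALSE, nrow(u))
  srcVals <- map@values
  srcVals[!map@valid] <- NA_real_
  d <- src@dim
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ci <- lo + matrix(c(dx, dy, dz), nrow(lo), 3, byrow = TRUE)
    wgt <- abs((1 - dx) - fr[, 1]) * abs((1 - dy) - fr[, 2]) *
           abs((1 - dz) - fr[, 3])
    inside <- ci[, 1] >= 0 & ci[, 1] < d[1] & ci[, 2] >= 0 &
              ci[, 2] < d[2] & ci[, 3] >= 0 & ci[, 3] < d[3]
    v <- rep(NA_real_, nrow(ci))
    if (any(inside))
      v[inside] <- srcVals[voxelToLinear(src, ci[inside, , drop = FALSE])]
    use <- wgt > 1e-12
    bad <- bad | (use & is.na(v))
    contrib <- ifelse(use & !is.na(v), wgt * v, 0)
    vals <- vals + contrib
    wsum <- wsum + ifelse(use & !is.na(v), wgt, 0)
  }
  out <- array(NA_real_, dim = target@dim)
  ok <- !bad & wsum > 1e-12
  out[ok] <- vals[ok] / wsum[ok]
  volumeMap(target, out, valid = array(ok, dim = target@dim))
}
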