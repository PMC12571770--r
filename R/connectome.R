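# Subject-level seed-to-voxel functional connectivity.

#' Fisher r-to-z transform with clipping
#'
#' `atanh` after clipping |r| to `1 - clipEps`, so perfect correlations map
#' to a large finite value instead of infinity. Undefined (NA) inputs
#' propagate.
#'
#' @param r correlations in [-1, 1] (any numeric shape).
#' @param clipEps clipping distance from |r| = 1; default 1e-7.
#' @return `atanh(clip(r))`, same shape as `r`.
#' @export
fisherZ <- function(r, clipEps = 1e-7) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
    stop("|r| must not exceed 1")
  atanh(pmin(pmax(r, -1 + clipEps), 1 - clipEps))
}

# rows of `data` matching a mask's voxels, given the subject's own mask
maskRows <- function(subject, roi) {
  roiOnGrid <- if (sameGrid(roi@grid, subject@grid)) roi else
    resampleMask(roi, subject@grid)
  idx <- which(roiOnGrid@values & subject@mask)
  match(idx, which(subject@mask))
}

#' Mean time course over a seed region
#'
#' Unweighted per-timepoint mean over the voxels of `seed` that fall inside
#' the subject's brain mask (the seed is resampled to the subject grid if
#' needed).
#'
#' @param seed a [VolumeMask-class].
#' @param subject a [SubjectTimeSeries-class].
#' @return Numeric vector of length `nTimepoints(subject)`. Errors when the
#'   seed does not intersect the brain mask.
#' @export
seedTimecourse <- function(seed, subject) {
  rows <- maskRows(subject, seed)
  if (length(rows) == 0L)
    stop(sprintf("seed '%s' has no voxels inside the brain mask",
                 seed@label))
  colMeans(subject@data[rows, , drop = FALSE])
}

#' Seed-to-voxel Pearson correlation map for one subject
#'
#' Pearson r between the seed time course and every in-mask voxel's series.
#' Zero-variance voxels are flagged undefined (not zero); a zero-variance
#' seed time course is an error because the correlation is undefined
#' everywhere.
#'
#' @param seedTc numeric seed time course, length `nTimepoints(subject)`.
#' @param subject a [SubjectTimeSeries-class].
#' @param seedLabel label recorded in the result.
#' @return An [FCMap-class] (a [VolumeMap-class] of r values with validity
#'   flags, plus seed/subject provenance).
#' @export
voxelwiseFC <- function(seedTc, subject, seedLabel = "seed") {
  X <- subject@data
  if (length(seedTc) != ncol(X))
    stop("seed time course length does not match the subject's timepoints")
  n <- length(seedTc)
  sc <- seedTc - mean(seedTc)
  ssS <- sum(sc^2)
  if (ssS <= 0)
    stop(sprintf(
      "seed '%s': time course has zero variance, correlation undefined",
      seedLabel))
  num <- as.vector(X %*% sc)
  rm <- rowMeans(X)
  ssV <- rowSums(X^2) - n * rm^2
  ssV[ssV < 0] <- 0            # guard tiny negative rounding
  ok <- ssV > n * 1e-24
  r <- rep(NA_real_, nrow(X))
  r[ok] <- num[ok] / sqrt(ssV[ok] * ssS)
  r <- pmin(pmax(r, -1), 1)
  vals <- array(NA_real_, dim = subject@grid@dim)
  valid <- array(FALSE, dim = subject@grid@dim)
  inIdx <- which(subject@mask)
  vals[inIdx] <- r
  valid[inIdx] <- ok
  new("FCMap", grid = subject@grid,
      values = vals, valid = valid,
      seedLabel = as.character(seedLabel),
      subjectId = subject@subjectId)
}

#' Lesion network stack: per-subject Fisher-z seed connectivity
#'
#' For every connectome subject, computes the seed-averaged time course,
#' correlates it with every in-brain voxel and applies the Fisher z
#' transform, preserving subject order. Deterministic given its inputs.
#'
#' @param seed a [VolumeMask-class] (lesion or stimulation-site ROI).
#' @param connectome a [NormativeConnectome-class].
#' @param clipEps Fisher-z clipping, see [fisherZ()].
#' @return A [ZMapStack-class] with one z layer per subject. A failure for
#'   any subject aborts with that subject's id.
#' @export
lesionNetwork <- function(seed, connectome, clipEps = 1e-7) {
  subs <- connectome@subjects
  V <- sum(connectome@brainMask@values)
  z <- matrix(NA_real_, length(subs), V)
  valid <- matrix(FALSE, length(subs), V)
  inIdx <- which(connectome@brainMask@values)
  for (s in seq_along(subs)) {
    sub <- subs[[s]]
    fc <- tryCatch({
      tc <- seedTimecourse(seed, sub)
      voxelwiseFC(tc, sub, seedLabel = seed@label)
    }, error = function(e) {
      stop(sprintf("subject '%s': %s", sub@subjectId, conditionMessage(e)),
           call. = FALSE)
    })
    rvec <- fc@values[inIdx]
    vvec <- fc@valid[inIdx]
    z[s, vvec] <- fisherZ(rvec[vvec], clipEps = clipEps)
    valid[s, ] <- vvec
  }
  new("ZMapStack", grid = connectome@grid, brainMask = connectome@brainMask,
      z = z, valid = valid, seedLabel = seed@label,
      subjectIds = vapply(subs, function(s) s@subjectId, character(1)))
}
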