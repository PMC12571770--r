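#' @import methods
NULL

# ---------------------------------------------------------------------------
# Volumetric data model
# ---------------------------------------------------------------------------

#' Voxel grid with a world affine
#'
#' An `ImageGrid` couples a 3-D voxel lattice with the 4x4 affine matrix that
#' maps 0-based voxel indices to world millimetre coordinates (RAS, the NIfTI
#' convention). All volumetric objects in the package carry one.
#'
#' @slot dim integer(3), voxels per axis.
#' @slot affine 4x4 numeric matrix, voxel-to-world (mm) transform.
#' @export
setClass("ImageGrid", representation(dim = "integer", affine = "matrix"))

setValidity("ImageGrid", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be 3 positive integers")
  a <- object@affine
  if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)))
    return("affine must be a 4x4 numeric matrix")
  if (!all(is.finite(a)))
    return("affine must be finite")
  if (max(abs(a[4, ] - c(0, 0, 0, 1))) > 1e-8)
    return("last affine row must be (0, 0, 0, 1)")
  if (abs(det(a[1:3, 1:3])) < 1e-12)
    return("affine is singular")
  if (any(sqrt(colSums(a[1:3, 1:3]^2)) <= 0))
    return("voxel spacing must be positive")
  TRUE
})

#' Construct an ImageGrid
#'
#' @param dim integer(3) voxel counts per axis.
#' @param affine optional 4x4 voxel-to-world matrix. When omitted an
#'   axis-aligned affine is built from `spacing` and `origin`.
#' @param spacing numeric(3) voxel size in mm (used when `affine` is missing).
#' @param origin world coordinate of voxel (0,0,0) (used when `affine` is
#'   missing).
#' @return An [ImageGrid-class] object.
#' @examples
#' g <- imageGrid(c(10, 10, 10), spacing = c(2, 2, 2))
#' gridSpacing(g)
#' @export
imageGrid <- function(dim, affine = NULL, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  if (is.null(affine)) {
    affine <- diag(4)
    affine[cbind(1:3, 1:3)] <- spacing
    affine[1:3, 4] <- origin
  }
  new("ImageGrid", dim = as.integer(dim), affine = unname(as.matrix(affine)))
}

#' @describeIn imageGrid voxel counts per axis.
#' @param grid an `ImageGrid`.
#' @export
gridDim <- function(grid) grid@dim

#' @describeIn imageGrid the 4x4 voxel-to-world affine.
#' @export
gridAffine <- function(grid) grid@affine

#' @describeIn imageGrid voxel spacing in mm, derived from the affine columns.
#' @export
gridSpacing <- function(grid) sqrt(colSums(grid@affine[1:3, 1:3]^2))

sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@dim, b@dim) && max(abs(a@affine - b@affine)) <= tol
}

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid %s, spacing %s mm\n",
              paste(object@dim, collapse = "x"),
              paste(signif(gridSpacing(object), 4), collapse = "x")))
})

#' Scalar volume on a grid
#'
#' A real value per voxel plus a validity flag marking voxels where the value
#' is defined (e.g. inside the brain mask, or where a correlation was
#' computable). Undefined voxels are never silently zero.
#'
#' @slot grid the [ImageGrid-class].
#' @slot values numeric 3-D array.
#' @slot valid logical 3-D array, TRUE where `values` is defined.
#' @export
setClass("VolumeMap",
         representation(grid = "ImageGrid", values = "array",
                        valid = "array"))

setValidity("VolumeMap", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@dim)))
    return("values shape must equal grid shape")
  if (!identical(dim(object@valid), dim(object@values)))
    return("valid shape must equal values shape")
  if (!is.logical(object@valid))
    return("valid must be logical")
  if (any(!is.finite(object@values[object@valid])))
    return("values must be finite where valid")
  TRUE
})

#' Construct a VolumeMap
#'
#' @param grid an [ImageGrid-class].
#' @param values numeric array matching the grid shape.
#' @param valid optional logical array of defined voxels; defaults to
#'   finite voxels.
#' @return A [VolumeMap-class].
#' @export
volumeMap <- function(grid, values, valid = NULL) {
  values <- array(as.double(values), dim = grid@dim)
  if (is.null(valid)) valid <- is.finite(values)
  valid <- array(as.logical(valid), dim = grid@dim)
  values[!valid] <- NA_real_
  new("VolumeMap", grid = grid, values = values, valid = valid)
}

#' Binary volume on a grid
#'
#' @slot grid the [ImageGrid-class].
#' @slot values logical 3-D array.
#' @slot label free-text identifier (lesion id, symptom class, ...).
#' @export
setClass("VolumeMask",
         representation(grid = "ImageGrid", values = "array",
                        label = "character"))

setValidity("VolumeMask", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@dim)))
    return("values shape must equal grid shape")
  if (!is.logical(object@values))
    return("mask values must be logical")
  TRUE
})

#' Construct a VolumeMask
#'
#' @param grid an [ImageGrid-class].
#' @param values logical (or 0/1) array matching the grid shape.
#' @param label identifier carried through the pipeline.
#' @return A [VolumeMask-class].
#' @export
volumeMask <- function(grid, values, label = "") {
  new("VolumeMask", grid = grid,
      values = array(as.logical(values), dim = grid@dim),
      label = as.character(label))
}

#' Number of voxels set in a mask
#' @param mask a [VolumeMask-class].
#' @export
maskCount <- function(mask) sum(mask@values)

#' Label carried by a mask
#' @param mask a [VolumeMask-class].
#' @export
maskLabel <- function(mask) mask@label

#' Values of a volumetric object
#' @param x a [VolumeMap-class], [VolumeMask-class] or related object.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
setMethod("mapValues", "VolumeMap", function(x) x@values)

#' @rdname mapValues
setMethod("mapValues", "VolumeMask", function(x) x@values)

#' Grid accessor
#' @param x any volumetric object in the package.
#' @export
setGeneric("imageGridOf", function(x) standardGeneric("imageGridOf"))

setMethod("imageGridOf", "ImageGrid", function(x) x)
setMethod("imageGridOf", "VolumeMap", function(x) x@grid)
setMethod("imageGridOf", "VolumeMask", function(x) x@grid)

setMethod("show", "VolumeMap", function(object) {
  cat(sprintf("VolumeMap %s: %d defined voxels, range [%.4g, %.4g]\n",
              paste(object@grid@dim, collapse = "x"), sum(object@valid),
              suppressWarnings(min(object@values, na.rm = TRUE)),
              suppressWarnings(max(object@values, na.rm = TRUE))))
})

setMethod("show", "VolumeMask", function(object) {
  cat(sprintf("VolumeMask %s '%s': %d voxels\n",
              paste(object@grid@dim, collapse = "x"), object@label,
              sum(object@values)))
})

#' Subject-level FC map
#'
#' Pearson correlation of one seed time course with every in-brain voxel of
#' one connectome subject. Voxels with zero variance are flagged undefined.
#'
#' @slot seedLabel label of the seed mask.
#' @slot subjectId connectome subject identifier.
#' @export
setClass("FCMap", contains = "VolumeMap",
         representation(seedLabel = "character", subjectId = "character"))

# ---------------------------------------------------------------------------
# Connectome
# ---------------------------------------------------------------------------

#' Resting-state time series of one connectome subject
#'
#' Stored masked: `data` holds one row per in-mask voxel, in the order given
#' by `which(mask)` (column-major), one column per timepoint.
#'
#' @slot subjectId identifier.
#' @slot grid the [ImageGrid-class].
#' @slot mask logical array of in-brain voxels.
#' @slot data numeric matrix, in-mask voxels x timepoints.
#' @export
setClass("SubjectTimeSeries",
         representation(subjectId = "character", grid = "ImageGrid",
                        mask = "array", data = "matrix"))

setValidity("SubjectTimeSeries", function(object) {
  if (!identical(dim(object@mask), as.integer(object@grid@dim)))
    return("mask shape must equal grid shape")
  if (nrow(object@data) != sum(object@mask))
    return("data must have one row per in-mask voxel")
  if (ncol(object@data) < 3L)
    return("need at least 3 timepoints")
  if (any(!is.finite(object@data)))
    return("time series must be finite")
  TRUE
})

#' Construct a SubjectTimeSeries
#'
#' @param subjectId identifier.
#' @param grid an [ImageGrid-class].
#' @param mask logical array of in-brain voxels.
#' @param data matrix with one row per in-mask voxel (order `which(mask)`)
#'   and one column per timepoint.
#' @return A [SubjectTimeSeries-class].
#' @export
subjectTimeSeries <- function(subjectId, grid, mask, data) {
  new("SubjectTimeSeries", subjectId = as.character(subjectId), grid = grid,
      mask = array(as.logical(mask), dim = grid@dim),
      data = as.matrix(data))
}

#' Number of timepoints
#' @param x a [SubjectTimeSeries-class].
#' @export
nTimepoints <- function(x) ncol(x@data)

#' Normative connectome: shared-grid collection of subject time series
#'
#' @slot grid shared [ImageGrid-class].
#' @slot brainMask shared brain [VolumeMask-class].
#' @slot subjects list of [SubjectTimeSeries-class], order preserved.
#' @export
setClass("NormativeConnectome",
         representation(grid = "ImageGrid", brainMask = "VolumeMask",
                        subjects = "list"))

setValidity("NormativeConnectome", function(object) {
  if (length(object@subjects) < 2L)
    return("need at least 2 subjects")
  ok <- vapply(object@subjects, function(s) {
    is(s, "SubjectTimeSeries") && sameGrid(s@grid, object@grid) &&
      identical(s@mask, object@brainMask@values)
  }, logical(1))
  if (!all(ok))
    return("all subjects must share the connectome grid and brain mask")
  TRUE
})

#' Construct a NormativeConnectome
#'
#' @param subjects list of [SubjectTimeSeries-class] sharing one grid/mask.
#' @param brainMask the shared brain [VolumeMask-class].
#' @return A [NormativeConnectome-class].
#' @export
normativeConnectome <- function(subjects, brainMask) {
  new("NormativeConnectome", grid = brainMask@grid, brainMask = brainMask,
      subjects = subjects)
}

#' Number of subjects in a connectome
#' @param x a [NormativeConnectome-class].
#' @export
nSubjects <- function(x) length(x@subjects)

setMethod("imageGridOf", "NormativeConnectome", function(x) x@grid)

setMethod("show", "NormativeConnectome", function(object) {
  cat(sprintf(
    "NormativeConnectome: %d subjects, grid %s, %d in-mask voxels, T=%d\n",
    length(object@subjects), paste(object@grid@dim, collapse = "x"),
    sum(object@brainMask@values), ncol(object@subjects[[1]]@data)))
})

#' Per-subject Fisher-z seed-connectivity stack
#'
#' One Fisher-z map per connectome subject for a single seed, stored masked
#' (columns follow `which(brainMask)`). `valid` flags voxels where the
#' correlation was defined for that subject.
#'
#' @slot grid the [ImageGrid-class].
#' @slot brainMask the brain [VolumeMask-class].
#' @slot z numeric matrix subjects x in-mask voxels.
#' @slot valid logical matrix, same shape as `z`.
#' @slot seedLabel label of the seed.
#' @slot subjectIds subject order, one per row of `z`.
#' @export
setClass("ZMapStack",
         representation(grid = "ImageGrid", brainMask = "VolumeMask",
                        z = "matrix", valid = "matrix",
                        seedLabel = "character", subjectIds = "character"))

setValidity("ZMapStack", function(object) {
  if (!identical(dim(object@z), dim(object@valid)))
    return("z and valid must have the same shape")
  if (nrow(object@z) != length(object@subjectIds))
    return("one row per subject id")
  if (ncol(object@z) != sum(object@brainMask@values))
    return("one column per in-mask voxel")
  if (any(!is.finite(object@z[object@valid])))
    return("z must be finite where valid")
  TRUE
})

setMethod("show", "ZMapStack", function(object) {
  cat(sprintf("ZMapStack '%s': %d subjects x %d in-mask voxels\n",
              object@seedLabel, nrow(object@z), ncol(object@z)))
})

# ---------------------------------------------------------------------------
# Group statistics
# ---------------------------------------------------------------------------

#' Voxelwise group t map
#'
#' @slot grid the [ImageGrid-class].
#' @slot t numeric array of t values (may contain +/-Inf where the group
#'   standard deviation is zero with a nonzero mean).
#' @slot valid logical array of defined voxels.
#' @slot df residual degrees of freedom.
#' @slot tail `"one"` or `"two"`, how downstream thresholds interpret t.
#' @export
setClass("GroupTMap",
         representation(grid = "ImageGrid", t = "array", valid = "array",
                        df = "numeric", tail = "character"))

setValidity("GroupTMap", function(object) {
  if (!identical(dim(object@t), as.integer(object@grid@dim)))
    return("t shape must equal grid shape")
  if (object@df < 1) return("df must be >= 1")
  if (!object@tail %in% c("one", "two")) return("tail must be one|two")
  TRUE
})

setMethod("imageGridOf", "GroupTMap", function(x) x@grid)

setMethod("show", "GroupTMap", function(object) {
  fin <- object@t[object@valid & is.finite(object@t)]
  cat(sprintf("GroupTMap df=%g (%s-tailed): %d defined voxels, max t %.3g\n",
              object@df, object@tail, sum(object@valid),
              if (length(fin)) max(fin) else NA))
})

#' Thresholded binary map with its provenance rule
#'
#' @slot grid the [ImageGrid-class].
#' @slot values logical array.
#' @slot rule the thresholding rule, recorded verbatim (e.g. `"t>7"`).
#' @export
setClass("BinarizedMap",
         representation(grid = "ImageGrid", values = "array",
                        rule = "character"))

setMethod("mapValues", "BinarizedMap", function(x) x@values)
setMethod("imageGridOf", "BinarizedMap", function(x) x@grid)

setMethod("show", "BinarizedMap", function(object) {
  cat(sprintf("BinarizedMap [%s]: %d voxels\n", object@rule,
              sum(object@values)))
})

#' Voxelwise overlap of binarized maps
#'
#' @slot grid the [ImageGrid-class].
#' @slot count integer array, number of maps containing each voxel.
#' @slot nMaps number of maps overlapped.
#' @export
setClass("OverlapMap",
         representation(grid = "ImageGrid", count = "array",
                        nMaps = "integer"))

#' @describeIn overlapMap per-voxel overlap fraction `count / nMaps`.
#' @param om an [OverlapMap-class].
#' @export
overlapFraction <- function(om) om@count / om@nMaps

setMethod("show", "OverlapMap", function(object) {
  cat(sprintf("OverlapMap of %d maps: max count %d\n", object@nMaps,
              max(object@count)))
})

#' Conjunction hub ROI
#'
#' Voxelwise intersection of a sensitivity and a specificity map, with the
#' provenance of both rules. `empty` flags a degenerate (voxel-free) hub.
#'
#' @slot mask the hub [VolumeMask-class].
#' @slot provenance character(2): sensitivity rule, specificity rule.
#' @slot empty TRUE when the conjunction contained no voxel.
#' @export
setClass("HubROI",
         representation(mask = "VolumeMask", provenance = "character",
                        empty = "logical"))

setMethod("show", "HubROI", function(object) {
  cat(sprintf("HubROI: %d voxels (%s AND %s)%s\n", sum(object@mask@values),
              object@provenance[1], object@provenance[2],
              if (object@empty) " [EMPTY]" else ""))
})

# ---------------------------------------------------------------------------
# Parcel-level objects
# ---------------------------------------------------------------------------

#' Integer-labelled parcellation volume
#'
#' @slot grid the [ImageGrid-class].
#' @slot labels integer array with 0 = background and labels 1..K.
#' @slot K number of parcels.
#' @slot names parcel names, length K.
#' @export
setClass("Parcellation",
         representation(grid = "ImageGrid", labels = "array", K = "integer",
                        names = "character"))

setValidity("Parcellation", function(object) {
  if (!identical(dim(object@labels), as.integer(object@grid@dim)))
    return("labels shape must equal grid shape")
  l <- object@labels
  if (any(l < 0L) || any(l > object@K))
    return("labels must lie in 0..K")
  if (length(object@names) != object@K)
    return("need one name per parcel")
  TRUE
})

#' Construct a Parcellation
#'
#' @param grid an [ImageGrid-class].
#' @param labels integer array (0 = background, 1..K parcels).
#' @param K number of parcels; defaults to `max(labels)`.
#' @param names optional parcel names.
#' @return A [Parcellation-class]. Labels in 1..K that never occur are
#'   permitted; downstream parcel vectors mark them missing.
#' @export
parcellation <- function(grid, labels, K = NULL, names = NULL) {
  labels <- array(as.integer(labels), dim = grid@dim)
  if (is.null(K)) K <- max(labels)
  if (is.null(names)) names <- sprintf("parcel%03d", seq_len(K))
  new("Parcellation", grid = grid, labels = labels, K = as.integer(K),
      names = as.character(names))
}

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation K=%d on grid %s (%d labelled voxels)\n",
              object@K, paste(object@grid@dim, collapse = "x"),
              sum(object@labels > 0L)))
})

#' K named scalar values, one per parcel
#'
#' The unit of parcel-level spatial correlation. Missing values mark empty
#' parcels.
#'
#' @slot name what the vector measures (map name).
#' @slot values numeric length-K vector, named by parcel, NA where missing.
#' @export
setClass("ParcelVector",
         representation(name = "character", values = "numeric"))

#' Construct a ParcelVector
#'
#' @param values numeric vector, one entry per parcel (NA = empty parcel).
#' @param name map name.
#' @param parcelNames optional names for the entries.
#' @return A [ParcelVector-class].
#' @export
parcelVector <- function(values, name = "", parcelNames = NULL) {
  values <- as.double(values)
  if (!is.null(parcelNames)) names(values) <- parcelNames
  new("ParcelVector", name = as.character(name), values = values)
}

#' @describeIn parcelVector the per-parcel values.
#' @param x a [ParcelVector-class].
#' @export
parcelValues <- function(x) x@values

#' @describeIn parcelVector number of parcels (including missing).
#' @export
nParcels <- function(x) length(x@values)

setMethod("show", "ParcelVector", function(object) {
  cat(sprintf("ParcelVector '%s': K=%d (%d missing)\n", object@name,
              length(object@values), sum(is.na(object@values))))
})

# ---------------------------------------------------------------------------
# MEG objects
# ---------------------------------------------------------------------------

#' Parcel-by-time sampled signal
#'
#' @slot data numeric matrix, parcels x samples.
#' @slot fs sampling rate in Hz.
#' @slot parcelNames one name per row.
#' @export
setClass("ParcelTimeSeries",
         representation(data = "matrix", fs = "numeric",
                        parcelNames = "character"))

setValidity("ParcelTimeSeries", function(object) {
  if (object@fs <= 0) return("fs must be positive")
  if (length(object@parcelNames) != nrow(object@data))
    return("one name per parcel row")
  TRUE
})

#' Construct a ParcelTimeSeries
#'
#' @param data matrix, parcels x samples.
#' @param fs sampling rate (Hz).
#' @param parcelNames optional row names.
#' @return A [ParcelTimeSeries-class].
#' @export
parcelTimeSeries <- function(data, fs, parcelNames = NULL) {
  data <- as.matrix(data)
  if (is.null(parcelNames))
    parcelNames <- sprintf("parcel%03d", seq_len(nrow(data)))
  new("ParcelTimeSeries", data = data, fs = as.double(fs),
      parcelNames = as.character(parcelNames))
}

#' @describeIn parcelTimeSeries sampling rate in Hz.
#' @param x a [ParcelTimeSeries-class].
#' @export
samplingRate <- function(x) x@fs

setMethod("show", "ParcelTimeSeries", function(object) {
  cat(sprintf("ParcelTimeSeries: %d parcels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

#' Frequency band definition
#'
#' @slot name band name (delta, theta, alpha, ...).
#' @slot fLo lower edge (Hz).
#' @slot fHi upper edge (Hz).
#' @export
setClass("BandDefinition",
         representation(name = "character", fLo = "numeric", fHi = "numeric"))

setValidity("BandDefinition", function(object) {
  if (!(object@fLo > 0 && object@fLo < object@fHi))
    return("need 0 < fLo < fHi")
  TRUE
})

#' Construct a BandDefinition
#' @param name band name.
#' @param fLo,fHi band edges in Hz, `0 < fLo < fHi`.
#' @return A [BandDefinition-class].
#' @export
bandDefinition <- function(name, fLo, fHi) {
  new("BandDefinition", name = as.character(name), fLo = as.double(fLo),
      fHi = as.double(fHi))
}

#' The six canonical MEG bands
#'
#' delta 2-4, theta 5-7, alpha 8-12, beta 15-29, low gamma 30-59 and high
#' gamma 60-90 Hz.
#'
#' @return Named list of [BandDefinition-class] objects.
#' @export
canonicalBands <- function() {
  list(delta = bandDefinition("delta", 2, 4),
       theta = bandDefinition("theta", 5, 7),
       alpha = bandDefinition("alpha", 8, 12),
       beta = bandDefinition("beta", 15, 29),
       lowgamma = bandDefinition("lowgamma", 30, 59),
       highgamma = bandDefinition("highgamma", 60, 90))
}

#' Symmetric parcel-by-parcel connectivity matrix
#'
#' @slot m K x K numeric matrix, diagonal NA, entries in [-1, 1] or NA.
#' @slot band the [BandDefinition-class] it was computed in.
#' @export
setClass("ConnectivityMatrix",
         representation(m = "matrix", band = "BandDefinition"))

setValidity("ConnectivityMatrix", function(object) {
  m <- object@m
  if (nrow(m) != ncol(m)) return("matrix must be square")
  off <- m[upper.tri(m)]
  if (any(abs(off[!is.na(off)]) > 1 + 1e-12))
    return("entries must lie in [-1, 1]")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-10)
    return("matrix must be symmetric")
  TRUE
})

#' @describeIn aec the underlying K x K matrix.
#' @param cm a [ConnectivityMatrix-class].
#' @export
connectivityValues <- function(cm) cm@m

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix %dx%d, band %s (%g-%g Hz)\n",
              nrow(object@m), ncol(object@m), object@band@name,
              object@band@fLo, object@band@fHi))
})

# ---------------------------------------------------------------------------
# Synthetic ground truth
# ---------------------------------------------------------------------------

#' Planted spatial network pattern
#'
#' Smooth voxelwise weight field in [0, 1] (maximum exactly 1) standing in
#' for the true symptom network; used for parameter-recovery validation.
#'
#' @slot grid the [ImageGrid-class].
#' @slot W numeric array of weights in [0, 1].
#' @slot brainMask the brain [VolumeMask-class] the weights live in.
#' @slot parcelW the parcel-level projection ([ParcelVector-class]), or a
#'   zero-length placeholder before a parcellation is attached.
#' @export
setClass("PlantedNetwork",
         representation(grid = "ImageGrid", W = "array",
                        brainMask = "VolumeMask", parcelW = "ParcelVector"))

setValidity("PlantedNetwork", function(object) {
  if (!identical(dim(object@W), as.integer(object@grid@dim)))
    return("W shape must equal grid shape")
  if (any(object@W < 0) || abs(max(object@W) - 1) > 1e-9)
    return("W must lie in [0, 1] with max exactly 1")
  TRUE
})

setMethod("show", "PlantedNetwork", function(object) {
  cat(sprintf("PlantedNetwork on grid %s: %d voxels with W > 0.1\n",
              paste(object@grid@dim, collapse = "x"),
              sum(object@W > 0.1)))
})

#' Synthetic study configuration
#'
#' Bundles every tunable of the synthetic-data generator: grid geometry,
#' connectome size and noise model, seed placement, parcellation and MEG
#' settings, and the master random seed. All generators are pure functions
#' of a config.
#'
#' @slot params named list of settings (see [synthConfig()]).
#' @export
setClass("SynthConfig", representation(params = "list"))

setMethod("show", "SynthConfig", function(object) {
  p <- object@params
  cat(sprintf(paste0(
    "SynthConfig: grid %s @ %g mm, %d subjects x %d timepoints,\n",
    "  noise sd %g (fwhm %g mm), %d case + %d control seeds, K=%d,\n",
    "  MEG fs=%g Hz x %g s, master seed %d\n"),
    paste(p$dim, collapse = "x"), p$spacing[1], p$nSubjects, p$nTimepoints,
    p$noiseSd, p$noiseFwhm, p$nCase, p$nControl, p$K, p$fs, p$duration,
    p$seed))
})
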