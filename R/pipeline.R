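# End-to-end lesion network mapping: seeds -> per-lesion network t maps ->
# sensitivity / specificity / conjunction hub.

#' Per-lesion network t maps
#'
#' Runs [lesionNetwork()] and [oneSampleTMap()] for every seed.
#'
#' @param seeds list of [VolumeMask-class].
#' @param connectome a [NormativeConnectome-class].
#' @param clipEps Fisher-z clipping.
#' @return List of [GroupTMap-class], one per seed, in order.
#' @export
mapLesionNetworks <- function(seeds, connectome, clipEps = 1e-7) {
  lapply(seeds, function(s)
    oneSampleTMap(lesionNetwork(s, connectome, clipEps = clipEps)))
}

#' Full sensitivity/specificity/conjunction analysis
#'
#' The complete group pipeline: per-lesion network t maps for both groups;
#' case maps binarized at a Bonferroni family-wise threshold
#' (`alphaThresh` over the in-mask voxels, rescaled to the connectome's
#' df instead of a fixed t cut calibrated to n = 1000); overlap and
#' sensitivity mask at `overlapFraction`; voxelwise two-sample specificity
#' test at `alphaFWE`; conjunction hub.
#'
#' @param caseSeeds,controlSeeds lists of [VolumeMask-class].
#' @param connectome a [NormativeConnectome-class].
#' @param alphaThresh FWE rate for per-lesion map binarization
#'   (default 0.05).
#' @param overlapFraction sensitivity consensus fraction (default 0.8,
#'   inclusive).
#' @param alphaFWE FWE rate of the specificity test (default 0.05).
#' @param alternative specificity test direction, see [specificityTMap()].
#' @return List with `caseTmaps`, `controlTmaps`, `caseBinarized`,
#'   `overlap`, `sensitivity`, `specificity` (tmap + mask) and `hub`.
#' @export
runLesionNetworkMapping <- function(caseSeeds, controlSeeds, connectome,
                                    alphaThresh = 0.05,
                                    overlapFraction = 0.8,
                                    alphaFWE = 0.05,
                                    alternative = "greater") {
  nvox <- sum(connectome@brainMask@values)
  caseTmaps <- mapLesionNetworks(caseSeeds, connectome)
  controlTmaps <- mapLesionNetworks(controlSeeds, connectome)
  caseBin <- lapply(caseTmaps, thresholdBinarize, alphaFWE = alphaThresh,
                    nComparisons = nvox)
  ov <- overlapMap(caseBin)
  sens <- sensitivityMask(ov, minFraction = overlapFraction)
  spec <- specificityTMap(caseTmaps, controlTmaps, alphaFWE = alphaFWE,
                          alternative = alternative)
  hub <- conjunctionHub(sens, spec$mask)
  list(caseTmaps = caseTmaps, controlTmaps = controlTmaps,
       caseBinarized = caseBin, overlap = ov, sensitivity = sens,
       specificity = spec, hub = hub)
}
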