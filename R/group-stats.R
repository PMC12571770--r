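# Group-level maps: t statistics, thresholding, overlap, conjunction,
# hub-seeded network, ROI-to-ROI specificity and subcortical peaks.

maskedToArray <- function(grid, brainMask, vec, fill = NA_real_) {
  a <- array(fill, dim = grid@dim)
  a[which(brainMask@values)] <- vec
  a
}

#' One-sample t map over a Fisher-z stack
#'
#' Per voxel, `t = mean(z) / (sd(z) / sqrt(n))` over the subjects whose
#' value is defined there, with the sample (n-1) standard deviation.
#' Voxels with zero spread and a nonzero mean get a signed infinite t
#' (still flagged valid so strict thresholds keep them); zero spread and
#' zero mean, or fewer than two defined subjects, are flagged undefined.
#'
#' @param stack a [ZMapStack-class] with at least two subjects.
#' @return A [GroupTMap-class] with `df = nSubjects - 1`, one-tailed.
#' @export
oneSampleTMap <- function(stack) {
  S <- nrow(stack@z)
  if (S < 2L) stop("need at least 2 subjects")
  z <- stack@z
  z[!stack@valid] <- NA_real_
  n <- colSums(stack@valid)
  m <- colMeans(z, na.rm = TRUE)
  dev <- sweep(z, 2, m)
  ss <- colSums(dev^2, na.rm = TRUE)
  sd <- sqrt(ss / pmax(n - 1, 1))
  t <- rep(NA_real_, ncol(z))
  valid <- n >= 2L
  zero <- valid & sd <= 0
  pos <- valid & sd > 0
  t[pos] <- m[pos] / (sd[pos] / sqrt(n[pos]))
  t[zero & m != 0] <- sign(m[zero & m != 0]) * Inf
  valid[zero & m == 0] <- FALSE
  new("GroupTMap", grid = stack@grid,
      t = maskedToArray(stack@grid, stack@brainMask, t),
      valid = maskedToArray(stack@grid, stack@brainMask, valid,
                            fill = FALSE),
      df = S - 1, tail = "one")
}

#' Threshold a t map into a binary map
#'
#' Positive-tail thresholding: a voxel enters the mask iff its t value is
#' strictly greater than the threshold. Supply either `tMin` directly, or
#' `alphaFWE` plus `nComparisons` to derive a Bonferroni family-wise
#' threshold from the one-tailed t quantile at `alphaFWE / nComparisons`
#' with the map's df.
#'
#' @param tmap a [GroupTMap-class].
#' @param tMin fixed t threshold (e.g. 7).
#' @param alphaFWE family-wise error rate; requires `nComparisons`.
#' @param nComparisons number of voxels in the Bonferroni family.
#' @return A [BinarizedMap-class] whose `rule` records the threshold.
#' @export
thresholdBinarize <- function(tmap, tMin = NULL, alphaFWE = NULL,
                              nComparisons = NULL) {
  if (is.null(tMin) == is.null(alphaFWE))
    stop("give exactly one of tMin or alphaFWE")
  if (!is.null(alphaFWE)) {
    if (is.null(nComparisons))
      stop("alphaFWE requires nComparisons")
    tMin <- stats::qt(alphaFWE / nComparisons, df = tmap@df,
                      lower.tail = FALSE)
    rule <- sprintf("t>%.4g (FWE %g over %d, df=%g)", tMin, alphaFWE,
                    as.integer(nComparisons), tmap@df)
  } else {
    rule <- sprintf("t>%g", tMin)
  }
  vals <- tmap@valid & !is.na(tmap@t) & tmap@t > tMin
  new("BinarizedMap", grid = tmap@grid,
      values = array(vals, dim = tmap@grid@dim), rule = rule)
}

#' Voxelwise overlap of binarized maps
#'
#' @param maps list of [BinarizedMap-class] on one shared grid.
#' @return An [OverlapMap-class] with per-voxel counts; the fraction is
#'   `count / nMaps` exactly.
#' @export
overlapMap <- function(maps) {
  if (length(maps) < 1L) stop("need at least one map")
  g <- imageGridOf(maps[[1]])
  for (m in maps) if (!sameGrid(imageGridOf(m), g))
    stop("all maps must share one grid")
  count <- Reduce(`+`, lapply(maps, function(m) m@values + 0L))
  new("OverlapMap", grid = g,
      count = array(as.integer(count), dim = g@dim),
      nMaps = length(maps))
}

#' Sensitivity mask from an overlap map
#'
#' Voxels present in at least `minFraction` of the maps. The comparison is
#' inclusive (`>=`): a voxel shared by 20 of 25 maps is inside the default
#' 80% mask, matching the convention that a 20/25 consensus counts as an
#' 80% overlap.
#'
#' @param om an [OverlapMap-class].
#' @param minFraction minimum overlap fraction, default 0.8.
#' @return A [BinarizedMap-class].
#' @export
sensitivityMask <- function(om, minFraction = 0.8) {
  vals <- overlapFraction(om) >= minFraction
  new("BinarizedMap", grid = om@grid, values = array(vals, dim = om@grid@dim),
      rule = sprintf("overlap>=%g%% of %d maps", 100 * minFraction,
                     om@nMaps))
}

groupArrays <- function(maps) {
  vals <- vapply(maps, function(m) as.vector(m@t), numeric(prod(maps[[1]]@grid@dim)))
  valid <- vapply(maps, function(m) as.vector(m@valid),
                  logical(prod(maps[[1]]@grid@dim)))
  list(vals = vals, valid = valid)
}

#' Voxelwise two-sample specificity test with FWE control
#'
#' Compares unthresholded per-lesion group t maps between a case and a
#' control group with a voxelwise two-sample t test (default: pooled
#' variance, one-tailed in the case > control direction), then binarizes at
#' a Bonferroni family-wise threshold over the jointly defined voxels.
#'
#' @param caseMaps,controlMaps lists of per-lesion [GroupTMap-class] (or
#'   any [VolumeMap-class]-shaped objects with `t`/`valid` slots), at least
#'   two per group, on one grid.
#' @param alphaFWE family-wise error rate for the Bonferroni threshold,
#'   default 0.05.
#' @param alternative `"greater"` (case > control, the default) or
#'   `"two.sided"`.
#' @param varEqual pooled variance when TRUE (default); Welch otherwise
#'   (per-voxel Welch-Satterthwaite df, thresholded with the most
#'   conservative df in the map).
#' @return `list(tmap = GroupTMap, mask = BinarizedMap)`. Voxels with zero
#'   pooled variance are flagged undefined.
#' @export
specificityTMap <- function(caseMaps, controlMaps, alphaFWE = 0.05,
                            alternative = c("greater", "two.sided"),
                            varEqual = TRUE) {
  alternative <- match.arg(alternative)
  if (length(caseMaps) < 2L || length(controlMaps) < 2L)
    stop("need at least two maps per group")
  g <- imageGridOf(caseMaps[[1]])
  for (m in c(caseMaps, controlMaps)) if (!sameGrid(imageGridOf(m), g))
    stop("all maps must share one grid")
  A <- groupArrays(caseMaps); B <- groupArrays(controlMaps)
  n1 <- length(caseMaps); n2 <- length(controlMaps)
  defined <- rowSums(A$valid) == n1 & rowSums(B$valid) == n2 &
    rowSums(is.finite(A$vals)) == n1 & rowSums(is.finite(B$vals)) == n2
  m1 <- rowMeans(A$vals); m2 <- rowMeans(B$vals)
  v1 <- (rowSums(A$vals^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(B$vals^2) - n2 * m2^2) / (n2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    dfv <- rep(df, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    dfv <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df <- min(dfv[defined & se > 0], na.rm = TRUE)
  }
  t <- rep(NA_real_, length(se))
  ok <- defined & se > 0
  t[ok] <- (m1[ok] - m2[ok]) / se[ok]
  valid <- ok
  tmap <- new("GroupTMap", grid = g, t = array(t, dim = g@dim),
              valid = array(valid, dim = g@dim), df = df,
              tail = if (alternative == "greater") "one" else "two")
  nvox <- sum(valid)
  alphaAdj <- if (alternative == "two.sided") alphaFWE / 2 else alphaFWE
  mask <- thresholdBinarize(tmap, alphaFWE = alphaAdj,
                            nComparisons = max(nvox, 1L))
  list(tmap = tmap, mask = mask)
}

#' Conjunction of sensitivity and specificity maps
#'
#' Voxelwise logical AND (the product of the two binary maps). An empty
#' result is returned (with a warning and `empty = TRUE`) rather than
#' raised as an error.
#'
#' @param sensitivity,specificity [BinarizedMap-class] objects on one grid.
#' @param label label for the hub mask.
#' @return A [HubROI-class] whose provenance records both rules.
#' @export
conjunctionHub <- function(sensitivity, specificity, label = "hub") {
  if (!sameGrid(sensitivity@grid, specificity@grid))
    stop("maps must share one grid")
  vals <- sensitivity@values & specificity@values
  empty <- sum(vals) == 0L
  if (empty) warning("conjunction hub is empty")
  new("HubROI",
      mask = volumeMask(sensitivity@grid, vals, label = label),
      provenance = c(sensitivity@rule, specificity@rule),
      empty = empty)
}

#' Standard-normal-equivalent z from a t statistic
#'
#' CDF matching through the one-tailed p value: `z = qnorm(pt(t, df))`,
#' computed on the log scale so very large |t| stays finite and monotone.
#'
#' @param t numeric t values.
#' @param df degrees of freedom.
#' @return z values, same shape as `t`.
#' @export
tToZ <- function(t, df) {
  z <- rep(NA_real_, length(t))
  ok <- !is.na(t)
  lp <- stats::pt(t[ok], df = df, lower.tail = FALSE, log.p = TRUE)
  z[ok] <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  if (!is.null(dim(t))) dim(z) <- dim(t)
  z
}

#' Network map seeded from a conjunction hub
#'
#' Seeds the hub back through the connectome ([lesionNetwork()] +
#' [oneSampleTMap()]) and converts the group t map to a normalized network
#' map: either standard-normal-equivalent z per voxel (`method = "tz"`,
#' the default) or the across-subject mean Fisher-z map
#' (`method = "meanz"`).
#'
#' @param hub a [HubROI-class] (nonempty).
#' @param connectome a [NormativeConnectome-class].
#' @param method `"tz"` or `"meanz"`.
#' @param clipEps Fisher-z clipping.
#' @return A [VolumeMap-class] (the symptom network map).
#' @export
networkFromHub <- function(hub, connectome, method = c("tz", "meanz"),
                           clipEps = 1e-7) {
  method <- match.arg(method)
  if (hub@empty || sum(hub@mask@values) == 0L)
    stop("hub is empty; cannot seed a network")
  stack <- lesionNetwork(hub@mask, connectome, clipEps = clipEps)
  if (method == "meanz") {
    z <- stack@z
    z[!stack@valid] <- NA_real_
    vec <- colMeans(z, na.rm = TRUE)
    vec[colSums(stack@valid) == 0L] <- NA_real_
    return(volumeMap(stack@grid,
                     maskedToArray(stack@grid, stack@brainMask, vec)))
  }
  tmap <- oneSampleTMap(stack)
  z <- tToZ(as.vector(tmap@t), df = tmap@df)
  z[!as.vector(tmap@valid)] <- NA_real_
  volumeMap(tmap@grid, array(z, dim = tmap@grid@dim))
}

#' ROI-to-ROI specificity test against a hub
#'
#' For every seed, computes the across-subject mean Fisher-z correlation
#' between the seed time course and the hub time course, then compares the
#' case and control samples with a pooled two-sample t test, one-tailed in
#' the case > control direction.
#'
#' @param caseSeeds,controlSeeds lists of [VolumeMask-class] (>= 2 each).
#' @param hub a [HubROI-class].
#' @param connectome a [NormativeConnectome-class].
#' @param clipEps Fisher-z clipping.
#' @return `list(samples, t, df, p)` where `samples` is a data frame with
#'   columns `seed`, `group`, `value` (one mean Fisher-z FC per seed).
#' @export
roiToRoiTest <- function(caseSeeds, controlSeeds, hub, connectome,
                         clipEps = 1e-7) {
  if (length(caseSeeds) < 2L || length(controlSeeds) < 2L)
    stop("need at least two seeds per group")
  seedValue <- function(seed) {
    tryCatch({
      vals <- vapply(connectome@subjects, function(sub) {
        a <- seedTimecourse(seed, sub)
        b <- seedTimecourse(hub@mask, sub)
        fisherZ(stats::cor(a, b), clipEps = clipEps)
      }, numeric(1))
      mean(vals)
    }, error = function(e) {
      stop(sprintf("seed '%s': %s", seed@label, conditionMessage(e)),
           call. = FALSE)
    })
  }
  caseV <- vapply(caseSeeds, seedValue, numeric(1))
  ctrlV <- vapply(controlSeeds, seedValue, numeric(1))
  samples <- data.frame(
    seed = c(vapply(caseSeeds, maskLabel, character(1)),
             vapply(controlSeeds, maskLabel, character(1))),
    group = rep(c("case", "control"), c(length(caseV), length(ctrlV))),
    value = c(caseV, ctrlV),
    stringsAsFactors = FALSE)
  ht <- stats::t.test(caseV, ctrlV, alternative = "greater",
                      var.equal = TRUE)
  list(samples = samples, t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

# 26-connectivity offsets (half, to build each undirected edge once)
halfOffsets26 <- function() {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
      (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
}

#' Suprathreshold peaks inside a subcortical mask
#'
#' Finds the connected components (26-connectivity) of
#' `{t > tMin}` intersected with `subcortical`, and reports one peak (the
#' maximum t) per component. Components are ordered by descending peak t;
#' within a component, ties go to the lexicographically smallest 0-based
#' voxel index.
#'
#' @param tmap a [GroupTMap-class].
#' @param subcortical a [VolumeMask-class] restricting the search.
#' @param tMin threshold (strict `>`), e.g. 11 for deep-brain hubs.
#' @return Data frame with columns `x`, `y`, `z` (peak world mm), `t`
#'   (peak value) and `size` (component voxel count); zero rows when
#'   nothing survives.
#' @export
subcorticalPeaks <- function(tmap, subcortical, tMin) {
  if (!sameGrid(tmap@grid, subcortical@grid))
    stop("t map and mask must share one grid")
  if (sum(subcortical@values) == 0L) stop("subcortical mask is empty")
  sel <- which(tmap@valid & !is.na(tmap@t) & tmap@t > tMin &
               subcortical@values)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      t = numeric(0), size = integer(0))
  if (length(sel) == 0L) return(empty)
  g <- tmap@grid
  ijk <- linearToVoxel(g, sel)
  selSet <- integer(prod(g@dim))
  selSet[sel] <- seq_along(sel)
  offs <- halfOffsets26()
  edges <- NULL
  for (o in seq_len(nrow(offs))) {
    off <- offs[o, ]
    nb <- sweep(ijk, 2, -off)  # ijk + off
    inb <- nb[, 1] >= 0 & nb[, 1] < g@dim[1] &
           nb[, 2] >= 0 & nb[, 2] < g@dim[2] &
           nb[, 3] >= 0 & nb[, 3] < g@dim[3]
    if (!any(inb)) next
    lin <- voxelToLinear(g, nb[inb, , drop = FALSE])
    hit <- selSet[lin] > 0L
    if (!any(hit)) next
    from <- which(inb)[hit]
    to <- selSet[lin[hit]]
    edges <- rbind(edges, cbind(from, to))
  }
  gr <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (!is.null(edges))
    gr <- igraph::add_edges(gr, t(edges))
  comp <- igraph::components(gr)$membership
  tv <- tmap@t[sel]
  res <- lapply(seq_len(max(comp)), function(ci) {
    members <- which(comp == ci)
    best <- members[tv[members] == max(tv[members])]
    if (length(best) > 1L) {
      ord <- order(ijk[best, 1], ijk[best, 2], ijk[best, 3])
      best <- best[ord[1]]
    }
    w <- voxelToWorld(g, ijk[best, ])
    data.frame(x = w[1], y = w[2], z = w[3], t = tv[best],
               size = length(members))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dice overlap coefficient of two binary volumes
#'
#' @param a,b [VolumeMask-class], [BinarizedMap-class] or logical arrays of
#'   one shape.
#' @return `2|A and B| / (|A| + |B|)`; NA when both are empty.
#' @export
diceCoefficient <- function(a, b) {
  av <- if (is.array(a) && is.logical(a)) a else mapValues(a)
  bv <- if (is.array(b) && is.logical(b)) b else mapValues(b)
  stopifnot(identical(dim(av), dim(bv)))
  denom <- sum(av) + sum(bv)
  if (denom == 0) return(NA_real_)
  2 * sum(av & bv) / denom
}
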