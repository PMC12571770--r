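# Parcel-level spatial correlation with FDR control.

#' Per-parcel means of a volumetric map
#'
#' Unweighted mean of the defined voxels in each parcel. When the map and
#' parcellation grids differ, the map is first resampled (trilinear) to the
#' parcellation grid. Parcels with no defined voxel are missing (NA).
#'
#' @param map a [VolumeMap-class].
#' @param parc a [Parcellation-class].
#' @param name name for the resulting vector; defaults to "map".
#' @return A [ParcelVector-class] of length K.
#' @export
parcelMeans <- function(map, parc, name = "map") {
  if (!sameGrid(map@grid, parc@grid)) map <- resampleMap(map, parc@grid)
  labs <- as.vector(parc@labels)
  if (!any(labs > 0L)) stop("parcellation has no non-background labels")
  use <- labs > 0L & as.vector(map@valid)
  sums <- rep(0, parc@K); counts <- rep(0L, parc@K)
  if (any(use)) {
    tab <- rowsum(as.vector(map@values)[use], labs[use])
    cnt <- rowsum(rep(1L, sum(use)), labs[use])
    idx <- as.integer(rownames(tab))
    sums[idx] <- tab[, 1]; counts[idx] <- cnt[, 1]
  }
  vals <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  parcelVector(vals, name = name, parcelNames = parc@names)
}

#' Fisher r-to-z transform of a parcel vector of correlations
#'
#' @param pv a [ParcelVector-class] with values in [-1, 1] (NA allowed).
#' @param clipEps clipping distance from |r| = 1.
#' @return A [ParcelVector-class] of z values.
#' @export
fisherZVector <- function(pv, clipEps = 1e-7) {
  parcelVector(fisherZ(pv@values, clipEps = clipEps),
               name = pv@name, parcelNames = names(pv@values))
}

#' Pearson spatial correlation of two parcel vectors
#'
#' Parcels missing in either vector are dropped pairwise; the two-tailed p
#' value comes from the t distribution with `n - 2` df, where n is the
#' number of shared parcels.
#'
#' @param a,b [ParcelVector-class] objects of equal length K.
#' @param name map name for the result row; defaults to `b`'s name.
#' @return One-row data frame with columns `map_name`, `r`, `p`, `q`
#'   (NA until an FDR family is formed) and `n`.
#' @export
spatialCorrelation <- function(a, b, name = NULL) {
  if (length(a@values) != length(b@values))
    stop("parcel vectors must have equal length")
  ok <- !is.na(a@values) & !is.na(b@values)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 shared parcels")
  x <- a@values[ok]; y <- b@values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a parcel vector; correlation undefined")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p <- min(max(p, .Machine$double.xmin), 1)
  data.frame(map_name = if (is.null(name)) b@name else name,
             r = r, p = p, q = NA_real_, n = n,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment across one family of tests.
#'
#' @param p numeric p values in (0, 1].
#' @return q values, same order as `p`.
#' @export
fdrBH <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlate a network map with a family of annotation maps
#'
#' One [spatialCorrelation()] per annotation map, with Benjamini-Hochberg
#' FDR applied across the family (e.g. all receptor maps together, or all
#' frequency-band maps together). Results keep the family's given order.
#'
#' @param network a [ParcelVector-class] (the symptom network).
#' @param family nonempty list of [ParcelVector-class] annotation maps.
#' @return Data frame with one row per map: `map_name`, `r`, `p`, `q`, `n`.
#' @export
batchCorrelate <- function(network, family) {
  if (length(family) < 1L) stop("family must be nonempty")
  rows <- lapply(family, function(m) {
    tryCatch(spatialCorrelation(network, m),
             error = function(e) stop(sprintf("map '%s': %s", m@name,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  out <- do.call(rbind, rows)
  out$q <- fdrBH(out$p)
  rownames(out) <- NULL
  out
}

#' Read a family of annotation parcel vectors from TSV
#'
#' Expects columns `parcel_id`, `name`, `value`; one vector per distinct
#' `name`, entries placed at `parcel_id` (1..K), missing parcels NA.
#'
#' @param path TSV file path.
#' @param K number of parcels; defaults to the largest `parcel_id`.
#' @return Named list of [ParcelVector-class].
#' @export
readAnnotationTSV <- function(path, K = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("parcel_id", "name", "value")
  if (!all(need %in% names(tab)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(K)) K <- max(tab$parcel_id)
  lapply(split(tab, tab$name), function(d) {
    v <- rep(NA_real_, K)
    v[d$parcel_id] <- d$value
    parcelVector(v, name = d$name[1])
  })
}
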