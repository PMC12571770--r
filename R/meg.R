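# Band-limited oscillation analysis: zero-phase filtering, Hilbert
# envelopes, amplitude envelope correlation, node strength, band power and
# the cross-band principal component.

# Fraction of samples dropped from each end of an envelope before any
# statistic, to discard analytic-signal edge artifacts.
EDGE_TRIM <- 0.05

trimIndices <- function(n, frac = EDGE_TRIM) {
  k <- floor(frac * n)
  seq.int(k + 1L, n - k)
}

checkBand <- function(band, fs) {
  if (!(band@fHi < fs / 2))
    stop(sprintf("band %s (%g-%g Hz) violates the Nyquist limit fs/2 = %g",
                 band@name, band@fLo, band@fHi, fs / 2))
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass applied to
#' every parcel; output length equals input length.
#'
#' @param ts a [ParcelTimeSeries-class].
#' @param band a [BandDefinition-class]; `fHi` must stay below Nyquist.
#' @return The filtered [ParcelTimeSeries-class].
#' @export
bandpassFilter <- function(ts, band) {
  checkBand(band, ts@fs)
  bf <- signal::butter(4, c(band@fLo, band@fHi) / (ts@fs / 2),
                       type = "pass")
  out <- t(apply(ts@data, 1, function(x) signal::filtfilt(bf, x)))
  parcelTimeSeries(out, ts@fs, ts@parcelNames)
}

# analytic signal via the frequency-domain Hilbert multiplier
analyticSignal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Amplitude envelope via the Hilbert transform
#'
#' Magnitude of the analytic signal of each (already band-limited) parcel
#' series. The envelope keeps full length; downstream statistics trim the
#' first and last 5% of samples ([trimIndices()] with the module constant)
#' to avoid edge artifacts.
#'
#' @param ts a band-limited [ParcelTimeSeries-class].
#' @return A [ParcelTimeSeries-class] of envelopes.
#' @export
hilbertEnvelope <- function(ts) {
  out <- t(apply(ts@data, 1, function(x) Mod(analyticSignal(x))))
  parcelTimeSeries(out, ts@fs, ts@parcelNames)
}

#' Amplitude envelope correlation (AEC)
#'
#' Band-passes the signal, computes Hilbert envelopes, trims 5% of samples
#' at each end, and correlates the envelopes of every parcel pair
#' (Pearson). Parcels with zero envelope variance yield an undefined (NA)
#' row and column.
#'
#' @param ts a [ParcelTimeSeries-class] with at least two parcels.
#' @param band a [BandDefinition-class].
#' @return A [ConnectivityMatrix-class] (symmetric, diagonal NA).
#' @export
aec <- function(ts, band) {
  if (nrow(ts@data) < 2L) stop("need at least two parcels")
  env <- hilbertEnvelope(bandpassFilter(ts, band))
  E <- env@data[, trimIndices(ncol(env@data)), drop = FALSE]
  vars <- apply(E, 1, stats::var)
  C <- matrix(NA_real_, nrow(E), nrow(E))
  ok <- vars > 0
  if (sum(ok) >= 2)
    C[ok, ok] <- stats::cor(t(E[ok, , drop = FALSE]))
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- NA_real_
  dimnames(C) <- list(ts@parcelNames, ts@parcelNames)
  new("ConnectivityMatrix", m = C, band = band)
}

#' Node strength of a connectivity matrix
#'
#' Per parcel, the mean of its defined off-diagonal entries; a parcel with
#' no defined entry is missing.
#'
#' @param cm a [ConnectivityMatrix-class] (or plain symmetric matrix).
#' @param name name for the resulting vector.
#' @return A [ParcelVector-class].
#' @export
nodeStrength <- function(cm, name = NULL) {
  m <- if (is(cm, "ConnectivityMatrix")) cm@m else as.matrix(cm)
  diag(m) <- NA_real_
  counts <- rowSums(!is.na(m))
  vals <- ifelse(counts > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  if (is.null(name))
    name <- if (is(cm, "ConnectivityMatrix"))
      paste0(cm@band@name, "_strength") else "strength"
  parcelVector(vals, name = name, parcelNames = rownames(m))
}

#' Band-limited envelope power map
#'
#' Per parcel, the mean squared trimmed Hilbert envelope of the band-passed
#' signal. For a pure tone of amplitude A inside the band this equals A^2.
#'
#' @param ts a [ParcelTimeSeries-class].
#' @param band a [BandDefinition-class].
#' @return A [ParcelVector-class] named `"<band>_power"`.
#' @export
bandPowerMap <- function(ts, band) {
  env <- hilbertEnvelope(bandpassFilter(ts, band))
  E <- env@data[, trimIndices(ncol(env@data)), drop = FALSE]
  parcelVector(rowMeans(E^2), name = paste0(band@name, "_power"),
               parcelNames = ts@parcelNames)
}

#' First principal component across frequency-specific connectivity
#'
#' Fisher r-to-z transforms each band's connectivity matrix, reduces each
#' to a node-strength vector (default) or to its vectorized upper triangle
#' (`method = "edges"`), and extracts the first principal component across
#' bands, returning one value per parcel. The component sign is fixed so
#' that it correlates positively with the mean strength map.
#'
#' @param cms list of [ConnectivityMatrix-class] (>= 2 bands, shared K).
#' @param method `"strength"` (parcels x bands PCA, the default) or
#'   `"edges"` (PCA over vectorized matrices; the loadings recombine the
#'   band matrices, whose node strength is returned).
#' @param clipEps Fisher-z clipping.
#' @return A [ParcelVector-class] named `"composite_pc1"`, with the
#'   explained variance fraction in attribute `"explained"` of its values.
#' @export
compositePC1 <- function(cms, method = c("strength", "edges"),
                         clipEps = 1e-7) {
  method <- match.arg(method)
  if (length(cms) < 2L) stop("need at least two bands")
  K <- nrow(cms[[1]]@m)
  for (cm in cms) if (nrow(cm@m) != K) stop("bands must share K")
  zmats <- lapply(cms, function(cm) fisherZ(cm@m, clipEps = clipEps))
  if (method == "strength") {
    X <- vapply(zmats, function(z) {
      diag(z) <- NA_real_
      rowMeans(z, na.rm = TRUE)
    }, numeric(K))                      # K x B
    if (any(!is.finite(X))) stop("undefined node strengths in input")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    if (pc$sdev[1] <= 0) stop("degenerate (rank-0) connectivity input")
    v <- pc$x[, 1]
    expl <- pc$sdev[1]^2 / sum(pc$sdev^2)
  } else {
    ut <- upper.tri(zmats[[1]])
    M <- vapply(zmats, function(z) z[ut], numeric(sum(ut)))  # edges x B
    M <- M[stats::complete.cases(M), , drop = FALSE]
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    if (pc$sdev[1] <= 0) stop("degenerate (rank-0) connectivity input")
    load <- pc$rotation[, 1]
    comb <- Reduce(`+`, Map(function(z, w) w * z, zmats, as.list(load)))
    diag(comb) <- NA_real_
    v <- rowMeans(comb, na.rm = TRUE)
    expl <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  meanStrength <- rowMeans(vapply(zmats, function(z) {
    diag(z) <- NA_real_
    rowMeans(z, na.rm = TRUE)
  }, numeric(K)))
  if (stats::sd(v) > 0 && stats::sd(meanStrength) > 0 &&
      stats::cor(v, meanStrength) < 0) v <- -v
  pv <- parcelVector(v, name = "composite_pc1",
                     parcelNames = rownames(cms[[1]]@m))
  attr(pv@values, "explained") <- expl
  pv
}
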