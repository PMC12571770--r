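# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; nothing is read from disk.

# small axis-aligned grid centred on the origin
tinyGrid <- function(d = c(8L, 8L, 8L), spacing = c(1, 1, 1)) {
  imageGrid(d, spacing = spacing, origin = -(d - 1) / 2 * spacing)
}

# subject with fully in-mask random series
randomSubject <- function(id = "s1", grid = tinyGrid(), Tn = 20,
                          mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = gridDim(grid))
  V <- sum(mask)
  subjectTimeSeries(id, grid, mask, matrix(rnorm(V * Tn), V, Tn))
}

randomConnectome <- function(nSub = 3, grid = tinyGrid(), Tn = 20) {
  mask <- array(TRUE, dim = gridDim(grid))
  subs <- lapply(seq_len(nSub), function(s)
    randomSubject(sprintf("s%d", s), grid, Tn, mask))
  normativeConnectome(subs, volumeMask(grid, mask, label = "brain"))
}

maskFromLinear <- function(grid, idx, label = "roi") {
  v <- array(FALSE, dim = gridDim(grid))
  v[idx] <- TRUE
  volumeMask(grid, v, label = label)
}

# fully valid ZMapStack over a synthetic 1-D grid (V voxels = columns)
makeStack <- function(z, grid = NULL) {
  V <- ncol(z)
  d <- c(V, 1L, 1L)
  if (is.null(grid)) grid <- imageGrid(d)
  mask <- volumeMask(grid, array(TRUE, dim = d), label = "brain")
  new("ZMapStack", grid = grid, brainMask = mask, z = z,
      valid = matrix(TRUE, nrow(z), V), seedLabel = "seed",
      subjectIds = sprintf("s%d", seq_len(nrow(z))))
}

# --- independent oracles -------------------------------------------------

# sphere membership by exhaustive scan over the whole grid
bruteSphereCount <- function(grid, centerWorld, radius) {
  cv <- worldToVoxel(grid, centerWorld)
  cw <- voxelToWorld(grid, cv)
  n <- 0L
  d <- gridDim(grid)
  for (k in 0:(d[3] - 1)) for (j in 0:(d[2] - 1)) for (i in 0:(d[1] - 1)) {
    w <- voxelToWorld(grid, c(i, j, k))
    if (sum((w - cw)^2) <= radius^2 + 1e-9) n <- n + 1L
  }
  n
}

# textbook per-voxel Pearson correlation loop
bruteVoxelCor <- function(seedTc, subject) {
  apply(subject@data, 1, function(x) suppressWarnings(cor(x, seedTc)))
}

# one-sample t per column
bruteOneSampleT <- function(z) {
  apply(z, 2, function(col) mean(col) / (sd(col) / sqrt(length(col))))
}

# pooled two-sample t per row of two matrices (voxels x n)
bruteTwoSampleT <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  sapply(seq_len(nrow(A)), function(v) {
    a <- A[v, ]; b <- B[v, ]
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  })
}

# Benjamini-Hochberg step-up from its definition
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# analytic-signal envelope by explicit quadrature construction (an
# independent route: shift every Fourier component by -90 degrees)
bruteEnvelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  freqs <- c(0, seq_len(n - 1))
  sgn <- ifelse(freqs == 0 | (n %% 2 == 0 & freqs == n / 2), 0,
                ifelse(freqs <= (n - 1) / 2 | (n %% 2 == 0 & freqs < n / 2),
                       1, -1))
  quad <- Re(fft(-1i * sgn * X, inverse = TRUE) / n)
  sqrt(x^2 + quad^2)
}

# cached default-scale synthetic study + pipeline result, shared by the
# heavier tests
.studyCache <- new.env(parent = emptyenv())

defaultStudy <- function() {
  if (is.null(.studyCache$study))
    .studyCache$study <- simulateStudy(synthConfig())
  .studyCache$study
}

defaultPipeline <- function() {
  if (is.null(.studyCache$lnm)) {
    st <- defaultStudy()
    .studyCache$lnm <- suppressWarnings(
      runLesionNetworkMapping(st$caseSeeds, st$controlSeeds,
                              st$connectome))
  }
  .studyCache$lnm
}
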