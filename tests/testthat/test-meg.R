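toneTS <- function(freq, fs = 250, dur = 20, amp = 1, K = 1, phase = 0) {
  tt <- (seq_len(fs * dur) - 1) / fs
  parcelTimeSeries(matrix(rep(amp * sin(2 * pi * freq * tt + phase),
                              each = K), K, byrow = FALSE), fs)
}

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  alpha <- canonicalBands()$alpha
  delta <- canonicalBands()$delta
  x <- toneTS(10)
  keep <- bandpassFilter(x, alpha)@data[1, ]
  kill <- bandpassFilter(x, delta)@data[1, ]
  core <- lnmapr:::trimIndices(length(keep))
  rmsIn <- sqrt(mean(keep[core]^2)) / sqrt(0.5)
  rmsOut <- sqrt(mean(kill[core]^2)) / sqrt(0.5)
  expect_gt(rmsIn, 0.95)    # < 5% attenuation in band
  expect_lt(rmsOut, 0.10)   # > 90% attenuation out of band

  zero <- parcelTimeSeries(matrix(0, 2, 1000), 250)
  expect_equal(bandpassFilter(zero, alpha)@data, matrix(0, 2, 1000),
               tolerance = 1e-12)
  expect_error(bandpassFilter(toneTS(10, fs = 100),
                              canonicalBands()$highgamma), "Nyquist")
})

test_that("Hilbert envelopes recover amplitudes and modulators", {
  fs <- 250
  tt <- (seq_len(fs * 20) - 1) / fs
  x <- parcelTimeSeries(matrix(2.5 * sin(2 * pi * 10 * tt), 1), fs)
  env <- hilbertEnvelope(x)@data[1, ]
  core <- lnmapr:::trimIndices(length(env))
  expect_true(all(abs(env[core] - 2.5) < 0.05))  # within 2% off the edges

  mod <- 1 + 0.5 * sin(2 * pi * 0.5 * tt)
  am <- parcelTimeSeries(matrix(mod * sin(2 * pi * 10 * tt), 1), fs)
  envAM <- hilbertEnvelope(am)@data[1, core]
  expect_gt(cor(envAM, mod[core]), 0.95)

  zero <- parcelTimeSeries(matrix(0, 1, 512), fs)
  expect_equal(hilbertEnvelope(zero)@data, matrix(0, 1, 512),
               tolerance = 1e-12)
})

test_that("AEC equals the Pearson correlation of independent envelopes", {
  set.seed(51)
  fs <- 250
  alpha <- canonicalBands()$alpha
  ts <- parcelTimeSeries(matrix(rnorm(4 * fs * 8), 4), fs)
  cm <- aec(ts, alpha)
  M <- connectivityValues(cm)
  expect_true(all(is.na(diag(M))))
  expect_equal(M, t(M), tolerance = 1e-12)

  # oracle: band-pass, then quadrature-constructed envelopes, then cor()
  bp <- bandpassFilter(ts, alpha)@data
  E <- t(apply(bp, 1, bruteEnvelope))
  E <- E[, lnmapr:::trimIndices(ncol(E))]
  expected <- cor(t(E))
  diag(expected) <- NA_real_
  expect_equal(unname(M), expected, tolerance = 1e-10)

  # identical parcels -> AEC 1
  same <- parcelTimeSeries(rbind(ts@data[1, ], ts@data[1, ]), fs)
  expect_equal(connectivityValues(aec(same, alpha))[1, 2], 1,
               tolerance = 1e-12)
})

test_that("a shared amplitude modulator couples parcels; noise does not", {
  fs <- 250
  tt <- (seq_len(fs * 20) - 1) / fs
  alpha <- canonicalBands()$alpha
  set.seed(52)
  mod <- 1 + 0.8 * sin(2 * pi * 0.4 * tt)
  x1 <- mod * sin(2 * pi * 10 * tt) + 0.1 * rnorm(length(tt))
  x2 <- mod * sin(2 * pi * 10 * tt + 2) + 0.1 * rnorm(length(tt))
  coupled <- aec(parcelTimeSeries(rbind(x1, x2), fs), alpha)
  expect_gt(connectivityValues(coupled)[1, 2], 0.8)

  # independent white noise: mean AEC near zero over replicates
  vals <- replicate(200, {
    ts <- parcelTimeSeries(matrix(rnorm(2 * 1000), 2), fs)
    connectivityValues(aec(ts, alpha))[1, 2]
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("node strength averages defined off-diagonal entries", {
  band <- canonicalBands()$alpha
  mk <- function(m) new("ConnectivityMatrix", m = m, band = band)
  const <- matrix(0.4, 5, 5); diag(const) <- NA
  expect_equal(unname(parcelValues(nodeStrength(mk(const)))), rep(0.4, 5))

  m3 <- matrix(c(NA, 0.2, -0.4, 0.2, NA, 0.6, -0.4, 0.6, NA), 3, 3)
  expect_equal(unname(parcelValues(nodeStrength(mk(m3)))),
               c((0.2 - 0.4) / 2, (0.2 + 0.6) / 2, (-0.4 + 0.6) / 2),
               tolerance = 1e-12)

  perm <- c(3, 1, 2)
  sPerm <- parcelValues(nodeStrength(mk(m3[perm, perm])))
  expect_equal(unname(sPerm), unname(parcelValues(nodeStrength(mk(m3))))[perm],
               tolerance = 1e-12)
})

test_that("band power equals squared envelope magnitude and scales as A^2", {
  x1 <- toneTS(10, amp = 1)
  x2 <- toneTS(10, amp = 2)
  alpha <- canonicalBands()$alpha
  p1 <- parcelValues(bandPowerMap(x1, alpha))
  p2 <- parcelValues(bandPowerMap(x2, alpha))
  expect_equal(unname(p1), 1, tolerance = 0.02)   # envelope^2 of unit tone
  expect_equal(unname(p2 / p1), 4, tolerance = 0.01)
  z <- parcelTimeSeries(matrix(0, 1, 2000), 250)
  expect_equal(unname(parcelValues(bandPowerMap(z, alpha))), 0,
               tolerance = 1e-20)
})

test_that("the cross-band PC1 recovers dominant structure", {
  set.seed(53)
  bands <- canonicalBands()
  mkcm <- function(m, b) {
    m <- (m + t(m)) / 2
    diag(m) <- NA
    new("ConnectivityMatrix", m = pmin(pmax(m, -0.99), 0.99), band = b)
  }
  base <- matrix(runif(64, -0.5, 0.5), 8, 8)
  cmA <- mkcm(base, bands$alpha)
  # all bands identical -> PC1 proportional to that strength map,
  # explained variance 100%
  cms <- list(cmA, mkcm(base, bands$beta), mkcm(base, bands$delta))
  pc <- compositePC1(cms)
  s <- parcelValues(nodeStrength(cmA))
  zs <- parcelValues(nodeStrength(mkcm(atanh(connectivityValues(cmA)),
                                       bands$alpha)))
  expect_gt(abs(cor(parcelValues(pc), zs)), 1 - 1e-10)
  expect_equal(attr(parcelValues(pc), "explained"), 1, tolerance = 1e-10)

  # orthogonal patterns with 4:1 variance -> PC1 aligns with the dominant
  u <- scale(rnorm(8)); v <- scale(residuals(lm(rnorm(8) ~ u)))
  mk <- function(vec, sc) mkcm(0.3 * sc * tcrossprod(vec) / 4, bands$alpha)
  cms2 <- c(lapply(1:3, function(i) mk(u, 2)),
            lapply(1:3, function(i) mk(v, 1)))
  pc2 <- parcelValues(compositePC1(cms2))
  strengthU <- parcelValues(nodeStrength(mk(u, 2)))
  cosine <- abs(sum(scale(pc2) * scale(strengthU))) /
    sqrt(sum(scale(pc2)^2) * sum(scale(strengthU)^2))
  expect_gt(cosine, 0.99)

  # band order permutation leaves PC1 unchanged
  pcPerm <- parcelValues(compositePC1(cms2[c(4, 1, 5, 2, 6, 3)]))
  expect_equal(unname(pcPerm), unname(parcelValues(compositePC1(cms2))),
               tolerance = 1e-10, ignore_attr = TRUE)

  # sign convention: positively correlated with the mean strength map
  expect_gt(cor(parcelValues(pc), zs), 0)
})
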