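smallCfg <- function(...) {
  synthConfig(dim = c(14L, 14L, 14L), nSubjects = 6L, nTimepoints = 60L,
              nCase = 4L, nControl = 4L, K = 12L, duration = 4,
              lesionVoxels = 8L, ...)
}

test_that("generators are pure functions of the master seed", {
  cfg <- smallCfg(seed = 101L)
  a <- makeConnectome(cfg)
  b <- makeConnectome(cfg)
  expect_identical(a$connectome@subjects[[3]]@data,
                   b$connectome@subjects[[3]]@data)
  expect_identical(a$planted@W, b$planted@W)

  sa <- makeSeeds(cfg, a$planted)
  sb <- makeSeeds(cfg, b$planted)
  expect_identical(lapply(sa$case, mapValues), lapply(sb$case, mapValues))

  other <- makeConnectome(smallCfg(seed = 102L))
  expect_false(identical(a$connectome@subjects[[1]]@data,
                         other$connectome@subjects[[1]]@data))
})

test_that("the noiseless limit gives perfect seed correlations on the network", {
  cfg <- smallCfg(noiseSd = 0, seed = 103L)
  mc <- makeConnectome(cfg)
  planted <- mc$planted
  inIdx <- which(mapValues(planted@brainMask))
  Wv <- planted@W[inIdx]
  seedVox <- inIdx[which.max(Wv)]
  seed <- maskFromLinear(imageGridOf(mc$connectome), seedVox)
  sub <- mc$connectome@subjects[[1]]
  fc <- voxelwiseFC(seedTimecourse(seed, sub), sub)
  rIn <- mapValues(fc)[inIdx][Wv > 0.05]
  expect_true(all(abs(rIn - 1) < 1e-9))
})

test_that("seed-voxel correlation follows the closed-form SNR relation", {
  cfg <- synthConfig(dim = c(16L, 16L, 16L), nSubjects = 40L,
                     nTimepoints = 150L, noiseSd = 1, noiseFwhm = 0,
                     seed = 104L)
  mc <- makeConnectome(cfg)
  planted <- mc$planted
  inIdx <- which(mapValues(planted@brainMask))
  Wv <- planted@W[inIdx]
  v1 <- which.max(Wv)
  # a voxel far from v1 so noise correlation is negligible (no smoothing
  # here anyway), with a mid-level weight
  v2 <- order(abs(Wv - 0.5))[1]
  w1 <- Wv[v1]; w2 <- Wv[v2]; s <- 1
  r0 <- (w1 * w2) / sqrt((w1^2 + s^2) * (w2^2 + s^2))
  rs <- vapply(mc$connectome@subjects, function(sub)
    cor(sub@data[v1, ], sub@data[v2, ]), numeric(1))
  mcErr <- 3 * (1 - r0^2) / sqrt((cfg@params$nTimepoints - 3) *
                                   length(rs))
  expect_lt(abs(mean(rs) - r0), mcErr + 0.02)
})

test_that("case seeds live on the pattern, control seeds off it", {
  cfg <- smallCfg(seed = 105L)
  mc <- makeConnectome(cfg)
  ss <- makeSeeds(cfg, mc$planted)
  W <- mc$planted@W
  caseW <- vapply(ss$case, function(s) mean(W[mapValues(s)]), numeric(1))
  ctrlW <- vapply(ss$control, function(s) mean(W[mapValues(s)]), numeric(1))
  expect_gt(min(caseW), max(ctrlW))
  # no overlap between any pair of seeds
  tot <- Reduce(`+`, lapply(c(ss$case, ss$control),
                            function(s) mapValues(s) + 0L))
  expect_lte(max(tot), 1L)
  # every seed nonempty
  expect_true(all(vapply(c(ss$case, ss$control), maskCount,
                         integer(1)) >= 1L))
})

test_that("impossible seed requests fail with a helpful error", {
  cfg <- synthConfig(dim = c(8L, 8L, 8L), nSubjects = 2L,
                     nTimepoints = 10L, nCase = 25L, nControl = 68L,
                     K = 5L, seed = 106L)
  gm <- lnmapr:::synthGrid(cfg)
  p <- plantedNetwork(gm$grid, gm$mask)
  expect_error(makeSeeds(cfg, p), "infeasible")
})

test_that("annotation vectors hit their target correlation in expectation", {
  cfg <- smallCfg(seed = 107L)
  gm <- lnmapr:::synthGrid(cfg)
  p <- plantedNetwork(gm$grid, gm$mask)
  parc <- makeParcellation(synthConfig(K = 100L, seed = 107L), gm$grid,
                           gm$mask)
  pw <- lnmapr:::projectPlanted(p, parc)@parcelW

  exact <- makeAnnotation(pw, 1, noiseSeed = 1)
  expect_equal(spatialCorrelation(pw, exact)$r, 1, tolerance = 1e-12)

  rs <- vapply(1:400, function(i)
    spatialCorrelation(pw, makeAnnotation(pw, 0.55, noiseSeed = i))$r,
    numeric(1))
  expect_lt(abs(mean(rs) - 0.55), 0.015)
  # spread close to the Fisher-z prediction (1 - rho^2)/sqrt(K - 3)
  expect_lt(abs(sd(rs) - (1 - 0.55^2) / sqrt(97)), 0.02)

  r0 <- vapply(1:400, function(i)
    spatialCorrelation(pw, makeAnnotation(pw, 0, noiseSeed = 1000 + i))$r,
    numeric(1))
  expect_lt(abs(mean(r0)), 0.02)
})

test_that("synthetic MEG carries the pattern only when c1 > 0", {
  cfg <- synthConfig(K = 100L, duration = 20, c1 = 0, seed = 108L)
  gm <- lnmapr:::synthGrid(cfg)
  p <- plantedNetwork(gm$grid, gm$mask)
  parc <- makeParcellation(cfg, gm$grid, gm$mask)
  pw <- lnmapr:::projectPlanted(p, parc)@parcelW
  megFlat <- makeMEG(cfg, pw)
  rFlat <- spatialCorrelation(pw, bandPowerMap(megFlat,
                                               canonicalBands()$alpha))$r
  expect_lt(abs(rFlat), 0.25)

  meg2 <- makeMEG(cfg, pw)
  expect_identical(megFlat@data, meg2@data)
  expect_error(makeMEG(synthConfig(fs = 120), pw), "fs")
})

test_that("generated objects satisfy downstream preconditions end to end", {
  cfg <- smallCfg(seed = 109L)
  st <- simulateStudy(cfg)
  expect_s4_class(st$connectome, "NormativeConnectome")
  expect_identical(nSubjects(st$connectome), 6L)
  expect_identical(nParcels(st$planted@parcelW), 12L)
  # a case seed maps through the full chain without error
  stack <- lesionNetwork(st$caseSeeds[[1]], st$connectome)
  tm <- oneSampleTMap(stack)
  bm <- thresholdBinarize(tm, alphaFWE = 0.05,
                          nComparisons = sum(mapValues(st$mask)))
  expect_s4_class(bm, "BinarizedMap")
  pm <- parcelMeans(volumeMap(st$grid, tm@t, valid = tm@valid),
                    st$parcellation)
  expect_identical(nParcels(pm), 12L)
})
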