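test_that("one-sample t maps match the brute-force formula", {
  set.seed(31)
  z <- matrix(rnorm(20 * 40), 20, 40)
  tm <- oneSampleTMap(makeStack(z))
  expect_equal(as.vector(tm@t), bruteOneSampleT(z), tolerance = 1e-10)
  expect_equal(tm@df, 19)
})

test_that("degenerate one-sample inputs are flagged, not silently numeric", {
  # identical nonzero layers: zero sd, nonzero mean -> +Inf, still valid
  z <- matrix(rep(c(0.5, -0.2, 0), each = 3), 3, 3)
  tm <- oneSampleTMap(makeStack(z))
  expect_identical(as.vector(tm@t)[1], Inf)
  expect_identical(as.vector(tm@t)[2], -Inf)
  expect_false(as.vector(tm@valid)[3])   # zero sd, zero mean -> undefined
  # antisymmetric pair -> t = 0 everywhere
  m <- rnorm(5)
  tm2 <- oneSampleTMap(makeStack(rbind(m, -m)))
  expect_equal(as.vector(tm2@t), rep(0, 5), tolerance = 1e-12)
})

test_that("thresholding is strictly greater-than and supports FWE quantiles", {
  z <- matrix(rnorm(10 * 4), 10, 4)
  tm <- oneSampleTMap(makeStack(z))
  tm@t[] <- c(7, 7.0001, 6.9999, -3)
  bm <- thresholdBinarize(tm, tMin = 7)
  expect_identical(as.vector(bm@values), c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(bm@rule, "t>7")

  # FWE threshold reproduces the inverted one-tailed t quantile
  tm@df <- 999
  bm2 <- thresholdBinarize(tm, alphaFWE = 1e-6, nComparisons = 230000)
  thr <- qt(1e-6 / 230000, df = 999, lower.tail = FALSE)
  expect_match(bm2@rule, sprintf("%.4g", thr), fixed = TRUE)

  tm@t[] <- -abs(tm@t)
  expect_identical(sum(thresholdBinarize(tm, tMin = 0)@values), 0L)
  expect_error(thresholdBinarize(tm), "exactly one")
  expect_error(thresholdBinarize(tm, alphaFWE = 0.05), "nComparisons")
})

test_that("overlap maps count per-voxel membership and are order-invariant", {
  set.seed(32)
  g <- imageGrid(c(30L, 1L, 1L))
  maps <- lapply(1:25, function(i)
    new("BinarizedMap", grid = g,
        values = array(runif(30) < 0.5, dim = c(30, 1, 1)),
        rule = "t>1"))
  om <- overlapMap(maps)
  expect_equal(as.vector(om@count),
               Reduce(`+`, lapply(maps, function(m) as.vector(m@values) + 0)))
  omPerm <- overlapMap(maps[sample(25)])
  expect_identical(om@count, omPerm@count)

  # 20 of 25 maps is exactly 80% and included (inclusive threshold)
  maps20 <- lapply(1:25, function(i)
    new("BinarizedMap", grid = g,
        values = array(c(i <= 20, rep(TRUE, 29)), dim = c(30, 1, 1)),
        rule = "t>1"))
  om20 <- overlapMap(maps20)
  expect_equal(overlapFraction(om20)[1, 1, 1], 0.8)
  sm <- sensitivityMask(om20, 0.8)
  expect_true(sm@values[1, 1, 1])
})

test_that("the specificity t map matches the brute-force pooled formula", {
  set.seed(33)
  g <- imageGrid(c(50L, 1L, 1L))
  mkmap <- function(v) new("GroupTMap", grid = g,
                           t = array(v, dim = c(50, 1, 1)),
                           valid = array(TRUE, dim = c(50, 1, 1)),
                           df = 9, tail = "one")
  A <- matrix(rnorm(50 * 8, mean = 0.3), 50, 8)
  B <- matrix(rnorm(50 * 6), 50, 6)
  res <- specificityTMap(lapply(seq_len(8), function(i) mkmap(A[, i])),
                         lapply(seq_len(6), function(i) mkmap(B[, i])))
  expect_equal(as.vector(res$tmap@t), bruteTwoSampleT(A, B),
               tolerance = 1e-10)
  expect_equal(res$tmap@df, 12)

  # identical groups -> t = 0, empty mask
  same <- lapply(seq_len(4), function(i) mkmap(A[, i]))
  res0 <- specificityTMap(same, same)
  expect_equal(max(abs(as.vector(res0$tmap@t))), 0, tolerance = 1e-12)
  expect_identical(sum(res0$mask@values), 0L)
})

test_that("conjunction is the voxelwise product with provenance", {
  g <- imageGrid(c(20L, 1L, 1L))
  set.seed(34)
  a <- new("BinarizedMap", grid = g,
           values = array(runif(20) < 0.5, dim = c(20, 1, 1)), rule = "A")
  b <- new("BinarizedMap", grid = g,
           values = array(runif(20) < 0.5, dim = c(20, 1, 1)), rule = "B")
  hub <- conjunctionHub(a, b)
  expect_identical(as.vector(hub@mask@values),
                   as.vector(a@values & b@values))
  expect_identical(hub@provenance, c("A", "B"))
  expect_identical(mapValues(conjunctionHub(a, a)@mask), a@values)

  disj <- new("BinarizedMap", grid = g,
              values = array(!a@values, dim = c(20, 1, 1)), rule = "notA")
  expect_warning(h0 <- conjunctionHub(a, disj), "empty")
  expect_true(h0@empty)
})

test_that("t-to-z conversion is CDF-matching, monotone and normal-limited", {
  expect_equal(tToZ(0, df = 10), 0, tolerance = 1e-12)
  t <- seq(-2, 2, by = 0.25)
  expect_equal(tToZ(t, df = 5000), t, tolerance = 1e-2)
  big <- tToZ(seq(1, 60, by = 1), df = 29)
  expect_true(all(diff(big) > 0))
  expect_true(all(is.finite(big)))
})

test_that("ROI-to-ROI statistics match hand-computed arithmetic", {
  set.seed(35)
  conn <- randomConnectome(nSub = 3, grid = tinyGrid(c(5L, 5L, 5L)),
                           Tn = 25)
  g <- imageGridOf(conn)
  hubMask <- maskFromLinear(g, c(3L, 4L), label = "hub")
  hub <- new("HubROI", mask = hubMask, provenance = c("a", "b"),
             empty = FALSE)
  seeds <- lapply(list(c(10L, 11L), c(20L), c(30L, 31L, 32L), c(40L)),
                  function(i) maskFromLinear(g, i, label = paste0("s", i[1])))
  res <- roiToRoiTest(seeds[1:2], seeds[3:4], hub, conn)

  handValue <- function(seed) {
    mean(sapply(conn@subjects, function(sub) {
      a <- colMeans(sub@data[which(mapValues(seed)), , drop = FALSE])
      b <- colMeans(sub@data[which(mapValues(hubMask)), , drop = FALSE])
      atanh(min(max(cor(a, b), -1 + 1e-7), 1 - 1e-7))
    }))
  }
  hv <- vapply(seeds, handValue, numeric(1))
  expect_equal(res$samples$value, hv, tolerance = 1e-12)
  n1 <- 2; n2 <- 2
  sp2 <- ((n1 - 1) * var(hv[1:2]) + (n2 - 1) * var(hv[3:4])) / (n1 + n2 - 2)
  tHand <- (mean(hv[1:2]) - mean(hv[3:4])) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(res$t, tHand, tolerance = 1e-12)
  expect_equal(res$p, pt(tHand, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups -> t = 0
  res0 <- roiToRoiTest(seeds[1:2], seeds[1:2], hub, conn)
  expect_equal(res0$t, 0, tolerance = 1e-12)
})

test_that("subcortical peaks find component maxima deterministically", {
  g <- tinyGrid(c(21L, 21L, 11L), spacing = c(1, 1, 1))
  d <- gridDim(g)
  co <- lnmapr:::linearToVoxel(g, seq_len(prod(d)))
  # Gaussian bump peaking at 12 at voxel (5,10,5), mirrored bump at (15,10,5)
  bump <- function(c0) 12 * exp(-rowSums(sweep(co, 2, c0)^2) / 4)
  tv <- array(pmax(bump(c(5, 10, 5)), bump(c(15, 10, 5))), dim = d)
  tmap <- new("GroupTMap", grid = g, t = tv,
              valid = array(TRUE, dim = d), df = 29, tail = "one")
  sub <- volumeMask(g, array(TRUE, dim = d), label = "subcortical")

  pk <- subcorticalPeaks(tmap, sub, tMin = 11)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$t, rep(12, 2), tolerance = 1e-9)
  centers <- voxelToWorld(g, rbind(c(5, 10, 5), c(15, 10, 5)))
  expect_equal(sort(pk$x), sort(centers[, 1]), tolerance = 1e-9)
  expect_equal(abs(pk$x[1]), abs(pk$x[2]), tolerance = 1e-9)  # mirrored

  expect_identical(nrow(subcorticalPeaks(tmap, sub, tMin = 13)), 0L)
})
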