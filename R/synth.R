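# Synthetic study generator: planted network, connectome, seeds,
# parcellation, annotations and MEG series. Every generator is a pure
# function of (config, master seed); per-object random streams are derived
# from the master seed so adding one object never perturbs the others.

#' Synthetic study configuration
#'
#' Defaults define the desk-scale study: a 24x28x24 grid at 2 mm, 30
#' connectome subjects with 200 timepoints each, unit-sd spatially smoothed
#' noise (4 mm FWHM) on top of a shared AR(1) latent signal, 25 case and 25
#' control seeds, a K = 100 parcellation, and 60 s of 250 Hz parcel series
#' whose alpha-band amplitude follows the planted pattern.
#'
#' @param dim integer(3) grid shape.
#' @param spacing numeric(3) voxel size (mm).
#' @param nSubjects connectome subjects.
#' @param nTimepoints fMRI timepoints per subject.
#' @param ar AR(1) coefficient of the shared latent signal.
#' @param noiseSd voxel noise standard deviation (the latent has unit sd,
#'   so this is 1/SNR at the network peak).
#' @param noiseFwhm spatial smoothing FWHM of the noise field (mm).
#' @param nCase,nControl seed counts.
#' @param qCase case seeds centre on voxels with planted weight above this
#'   in-mask quantile.
#' @param qCtrl control seeds centre on voxels below this quantile.
#' @param sphereFraction fraction of each seed list built as 3-mm spheres
#'   (stimulation-site-like); the rest are irregular grown blobs
#'   (lesion-like). Default 0.24 (6 of 25).
#' @param lesionVoxels target voxel count of a blob seed.
#' @param K parcels in the synthetic parcellation.
#' @param fs MEG sampling rate (Hz).
#' @param duration MEG duration (s).
#' @param c0,c1 MEG alpha-tone amplitude is `c0 + c1 * parcelW`.
#' @param megNoiseSd broadband MEG noise sd.
#' @param seed master random seed (integer below 2^31).
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(dim = c(24L, 28L, 24L), spacing = c(2, 2, 2),
                        nSubjects = 30L, nTimepoints = 200L, ar = 0.4,
                        noiseSd = 1, noiseFwhm = 4,
                        nCase = 25L, nControl = 25L,
                        qCase = 0.9, qCtrl = 0.3, sphereFraction = 0.24,
                        lesionVoxels = 15L, K = 100L,
                        fs = 250, duration = 60, c0 = 0.5, c1 = 1.5,
                        megNoiseSd = 1, seed = 42L) {
  p <- list(dim = as.integer(dim), spacing = as.double(spacing),
            nSubjects = as.integer(nSubjects),
            nTimepoints = as.integer(nTimepoints), ar = ar,
            noiseSd = noiseSd, noiseFwhm = noiseFwhm,
            nCase = as.integer(nCase), nControl = as.integer(nControl),
            qCase = qCase, qCtrl = qCtrl, sphereFraction = sphereFraction,
            lesionVoxels = as.integer(lesionVoxels), K = as.integer(K),
            fs = fs, duration = duration, c0 = c0, c1 = c1,
            megNoiseSd = megNoiseSd, seed = as.integer(seed))
  stopifnot(all(p$dim >= 1L), all(p$spacing > 0), p$nSubjects >= 2L,
            p$nTimepoints >= 3L, abs(p$ar) < 1, p$noiseSd >= 0,
            p$nCase >= 1L, p$nControl >= 1L,
            p$qCase > 0 && p$qCase < 1, p$qCtrl > 0 && p$qCtrl < 1,
            p$sphereFraction >= 0 && p$sphereFraction <= 1,
            p$K >= 1L, p$fs > 0, p$duration > 0)
  new("SynthConfig", params = p)
}

#' @describeIn synthConfig access one configuration field.
#' @param cfg a [SynthConfig-class].
#' @param field field name.
#' @export
configField <- function(cfg, field) cfg@params[[field]]

# deterministic child seed derived from the master seed, a stream tag and
# an index; stays below 2^31
childSeed <- function(master, tag, i = 0L) {
  m <- 2147483563
  h <- as.double(master %% m)
  for (c in utf8ToInt(tag)) h <- (h * 131 + c) %% m
  h <- (h * 131 + as.double(i)) %% m
  as.integer(h)
}

#' Synthetic grid and ellipsoidal brain mask
#'
#' @param cfg a [SynthConfig-class].
#' @return `list(grid, mask)`: the [ImageGrid-class] (axis-aligned affine
#'   centred on the origin) and an ellipsoidal brain [VolumeMask-class]
#'   with semi-axes 85% of the half field of view.
#' @export
synthGrid <- function(cfg) {
  d <- configField(cfg, "dim"); sp <- configField(cfg, "spacing")
  origin <- -(d - 1) / 2 * sp
  grid <- imageGrid(d, spacing = sp, origin = origin)
  ctr <- (d - 1) / 2
  semi <- 0.85 * (d - 1) / 2
  co <- linearToVoxel(grid, seq_len(prod(d)))
  inside <- ((co[, 1] - ctr[1]) / semi[1])^2 +
            ((co[, 2] - ctr[2]) / semi[2])^2 +
            ((co[, 3] - ctr[3]) / semi[3])^2 <= 1
  list(grid = grid,
       mask = volumeMask(grid, array(inside, dim = d), label = "brain"))
}

#' Plant a smooth two-blob network pattern
#'
#' Two Gaussian blobs (5 mm sd, amplitudes 1 and 0.9) at fixed fractional
#' positions of the field of view, restricted to the brain mask and
#' normalized to a maximum of exactly 1. Deterministic: the pattern is part
#' of the study design, not of the random streams.
#'
#' @param grid an [ImageGrid-class].
#' @param mask the brain [VolumeMask-class].
#' @param blobSd blob standard deviation in mm.
#' @return A [PlantedNetwork-class] (parcel projection unset).
#' @export
plantedNetwork <- function(grid, mask, blobSd = 5) {
  d <- grid@dim; sp <- gridSpacing(grid)
  centersFrac <- rbind(c(0.34, 0.42, 0.50), c(0.66, 0.60, 0.52))
  amps <- c(1, 0.9)
  co <- linearToVoxel(grid, seq_len(prod(d)))
  mm <- sweep(co, 2, sp, `*`)
  W <- rep(0, nrow(co))
  for (b in seq_len(nrow(centersFrac))) {
    cmm <- centersFrac[b, ] * (d - 1) * sp
    d2 <- rowSums(sweep(mm, 2, cmm)^2)
    W <- pmax(W, amps[b] * exp(-d2 / (2 * blobSd^2)))
  }
  W[!as.vector(mask@values)] <- 0
  W <- W / max(W)
  new("PlantedNetwork", grid = grid, W = array(W, dim = d),
      brainMask = mask, parcelW = parcelVector(numeric(0), name = "W"))
}

# periodic Gaussian smoothing kernel in Fourier space; scale makes unit-sd
# white noise come out with unit sd after filtering
smoothingOperator <- function(d, spacing, fwhm) {
  if (fwhm <= 0) return(NULL)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  k1 <- lapply(1:3, function(a) {
    x <- seq_len(d[a]) - 1
    x <- pmin(x, d[a] - x) * spacing[a]
    exp(-x^2 / (2 * sigma^2))
  })
  ker <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  H <- stats::fft(array(ker, dim = d))
  scale <- sqrt(mean(Mod(H)^2))
  list(H = H, scale = scale)
}

smoothNoise <- function(d, op) {
  w <- array(stats::rnorm(prod(d)), dim = d)
  if (is.null(op)) return(w)
  Re(stats::fft(stats::fft(w) * op$H, inverse = TRUE)) /
    (prod(d) * op$scale)
}

arOne <- function(n, phi) {
  e <- stats::rnorm(n)
  a <- numeric(n)
  a[1] <- e[1]
  if (n > 1) for (t in 2:n) a[t] <- phi * a[t - 1] + sqrt(1 - phi^2) * e[t]
  a
}

#' Generate the synthetic normative connectome
#'
#' Each subject's voxel series is `x[v, t] = W[v] * a_s(t) + eps[v, t]`
#' with a unit-variance AR(1) latent `a_s` shared across voxels (the
#' planted network signal) and spatially smoothed Gaussian noise of sd
#' `noiseSd`. Subjects are independent; the whole dataset is a
#' deterministic function of the master seed.
#'
#' @param cfg a [SynthConfig-class].
#' @return `list(connectome, planted)`: the
#'   [NormativeConnectome-class] and the [PlantedNetwork-class].
#' @export
makeConnectome <- function(cfg) {
  gm <- synthGrid(cfg)
  planted <- plantedNetwork(gm$grid, gm$mask)
  d <- configField(cfg, "dim")
  Tn <- configField(cfg, "nTimepoints")
  sdN <- configField(cfg, "noiseSd")
  op <- smoothingOperator(d, configField(cfg, "spacing"),
                          configField(cfg, "noiseFwhm"))
  inIdx <- which(gm$mask@values)
  Wm <- planted@W[inIdx]
  subjects <- vector("list", configField(cfg, "nSubjects"))
  for (s in seq_along(subjects)) {
    set.seed(childSeed(configField(cfg, "seed"), "subject", s))
    a <- arOne(Tn, configField(cfg, "ar"))
    X <- matrix(0, length(inIdx), Tn)
    for (t in seq_len(Tn)) {
      eps <- if (sdN > 0) sdN * smoothNoise(d, op)[inIdx] else 0
      X[, t] <- Wm * a[t] + eps
    }
    subjects[[s]] <- subjectTimeSeries(sprintf("sub%03d", s), gm$grid,
                                       gm$mask@values, X)
  }
  list(connectome = normativeConnectome(subjects, gm$mask),
       planted = planted)
}

growBlob <- function(grid, startLin, size, allowed, occupied) {
  d <- grid@dim
  blob <- startLin
  frontier <- startLin
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  while (length(blob) < size) {
    cand <- unique(unlist(lapply(frontier, function(l) {
      ijk <- linearToVoxel(grid, l)
      nb <- sweep(off, 2, -as.numeric(ijk))
      inb <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 &
             nb[, 2] < d[2] & nb[, 3] >= 0 & nb[, 3] < d[3]
      voxelToLinear(grid, nb[inb, , drop = FALSE])
    })))
    cand <- setdiff(cand[allowed[cand] & !occupied[cand]], blob)
    if (length(cand) == 0L) break
    add <- cand[sample.int(length(cand), min(length(cand),
                                             size - length(blob)))]
    blob <- c(blob, add)
    frontier <- add
  }
  blob
}

#' Place case and control seeds on the planted pattern
#'
#' Case seeds centre on voxels whose planted weight exceeds the `qCase`
#' in-mask quantile; control seeds on voxels below the `qCtrl` quantile.
#' A `sphereFraction` share of each list are 3-mm-radius spheres
#' (stimulation-site-like); the rest are irregular blobs grown by a random
#' walk inside the same weight stratum (lesion-like). Seeds never overlap
#' and centres keep a minimum 3-voxel separation.
#'
#' @param cfg a [SynthConfig-class].
#' @param planted the [PlantedNetwork-class].
#' @param qCase,qCtrl optional quantile overrides (e.g. for null
#'   calibrations where both groups must come from one stratum).
#' @return `list(case, control)`: lists of [VolumeMask-class].
#' @export
makeSeeds <- function(cfg, planted, qCase = NULL, qCtrl = NULL) {
  if (is.null(qCase)) qCase <- configField(cfg, "qCase")
  if (is.null(qCtrl)) qCtrl <- configField(cfg, "qCtrl")
  grid <- planted@grid
  maskIdx <- which(planted@brainMask@values)
  Wv <- planted@W[maskIdx]
  thrCase <- stats::quantile(Wv, qCase)
  thrCtrl <- stats::quantile(Wv, qCtrl)
  # lesion-like blobs extend beyond the centre stratum: case blobs may
  # grow through the upper half of the weight distribution, control blobs
  # stay in the low stratum
  thrGrow <- stats::quantile(Wv, min(qCase, (qCase + qCtrl) / 2))
  allowedCase <- allowedCtrl <- growCase <- logical(prod(grid@dim))
  allowedCase[maskIdx[Wv >= thrCase]] <- TRUE
  growCase[maskIdx[Wv >= thrGrow]] <- TRUE
  allowedCtrl[maskIdx[Wv <= thrCtrl]] <- TRUE
  occupied <- logical(prod(grid@dim))
  set.seed(childSeed(configField(cfg, "seed"), "seeds"))
  minSep <- 2
  placeGroup <- function(n, allowed, grow, prefix) {
    cand <- sample(which(allowed))
    centers <- matrix(numeric(0), 0, 3)
    seeds <- vector("list", n)
    nSphere <- round(configField(cfg, "sphereFraction") * n)
    for (i in seq_len(n)) {
      center <- NA_integer_
      for (l in cand) {
        if (occupied[l]) next
        ijk <- linearToVoxel(grid, l)
        if (nrow(centers) > 0 &&
            min(sqrt(rowSums(sweep(centers, 2,
                                   as.numeric(ijk))^2))) < minSep) next
        center <- l
        break
      }
      if (is.na(center))
        stop(sprintf(
          "infeasible seed placement for '%s%02d': reduce seed counts or enlarge the grid",
          prefix, i))
      centers <- rbind(centers, as.numeric(linearToVoxel(grid, center)))
      label <- sprintf("%s%02d", prefix, i)
      if (i <= nSphere) {
        sp <- sphereROI(grid, voxelToWorld(grid, linearToVoxel(grid,
                                                               center)),
                        radius = 3, label = label)
        vox <- which(sp@values & !occupied &
                     as.vector(planted@brainMask@values))
        if (length(vox) == 0L) vox <- center
      } else {
        vox <- growBlob(grid, center, configField(cfg, "lesionVoxels"),
                        grow, occupied)
      }
      if (length(vox) < 1L)
        stop(sprintf("infeasible seed placement for '%s'", label))
      occupied[vox] <<- TRUE
      vals <- array(FALSE, dim = grid@dim)
      vals[vox] <- TRUE
      seeds[[i]] <- volumeMask(grid, vals, label = label)
    }
    seeds
  }
  case <- placeGroup(configField(cfg, "nCase"), allowedCase, growCase,
                     "case")
  control <- placeGroup(configField(cfg, "nControl"), allowedCtrl,
                        allowedCtrl, "ctrl")
  list(case = case, control = control)
}

#' Synthetic parcellation of the brain mask
#'
#' K spatially compact parcels from k-means on in-mask voxel world
#' coordinates; deterministic given the master seed.
#'
#' @param cfg a [SynthConfig-class].
#' @param grid the synthetic [ImageGrid-class].
#' @param mask the brain [VolumeMask-class].
#' @return A [Parcellation-class].
#' @export
makeParcellation <- function(cfg, grid, mask) {
  idx <- which(mask@values)
  co <- voxelToWorld(grid, linearToVoxel(grid, idx))
  set.seed(childSeed(configField(cfg, "seed"), "parcellation"))
  K <- configField(cfg, "K")
  km <- suppressWarnings(stats::kmeans(co, centers = K, iter.max = 500,
                                       nstart = 1))
  labels <- array(0L, dim = grid@dim)
  labels[idx] <- km$cluster
  parcellation(grid, labels, K = K)
}

#' Attach the parcel-level projection to a planted network
#'
#' @param planted a [PlantedNetwork-class].
#' @param parc a [Parcellation-class].
#' @return The [PlantedNetwork-class] with `parcelW` set to the per-parcel
#'   mean of W.
#' @export
projectPlanted <- function(planted, parc) {
  w <- parcelMeans(volumeMap(planted@grid, planted@W,
                             valid = planted@brainMask@values),
                   parc, name = "plantedW")
  planted@parcelW <- w
  planted
}

#' Annotation vector with a target correlation to the planted pattern
#'
#' `y = targetR * standardize(parcelW) + sqrt(1 - targetR^2) * noise` with
#' independent standard normal noise, so the expected sample correlation
#' with the planted parcel pattern is `targetR` (exactly +/-1 when
#' `|targetR| = 1`).
#'
#' @param parcelW the planted [ParcelVector-class] pattern.
#' @param targetR target Pearson correlation in [-1, 1].
#' @param noiseSeed integer seed for this annotation's noise stream.
#' @param name map name.
#' @return A [ParcelVector-class] (missing where `parcelW` is missing).
#' @export
makeAnnotation <- function(parcelW, targetR, noiseSeed, name = "annotation") {
  stopifnot(abs(targetR) <= 1)
  w <- parcelW@values
  ok <- !is.na(w)
  if (sum(ok) < 3L) stop("need at least 3 parcels")
  if (stats::sd(w[ok]) == 0) stop("planted parcel pattern has zero variance")
  sW <- as.vector(scale(w[ok]))
  set.seed(noiseSeed)
  noise <- stats::rnorm(sum(ok))
  y <- rep(NA_real_, length(w))
  y[ok] <- targetR * sW + sqrt(1 - targetR^2) * noise
  parcelVector(y, name = name, parcelNames = names(w))
}

#' Synthetic MEG parcel time series with an alpha-specific pattern
#'
#' Parcel k carries a 10 Hz tone of amplitude `c0 + c1 * parcelW[k]` with a
#' random phase, plus broadband white noise, so only the alpha band's
#' spatial power map follows the planted pattern.
#'
#' @param cfg a [SynthConfig-class].
#' @param parcelW the planted [ParcelVector-class] (NA treated as 0).
#' @return A [ParcelTimeSeries-class] of `K` parcels at `fs` Hz.
#' @export
makeMEG <- function(cfg, parcelW) {
  fs <- configField(cfg, "fs")
  if (!(fs > 2 * 90))
    stop("fs must exceed twice the highest canonical band edge (90 Hz)")
  n <- round(fs * configField(cfg, "duration"))
  tt <- (seq_len(n) - 1) / fs
  w <- parcelW@values
  w[is.na(w)] <- 0
  K <- length(w)
  set.seed(childSeed(configField(cfg, "seed"), "meg"))
  phases <- stats::runif(K, 0, 2 * pi)
  amp <- configField(cfg, "c0") + configField(cfg, "c1") * w
  data <- matrix(stats::rnorm(K * n, sd = configField(cfg, "megNoiseSd")),
                 K, n)
  for (k in seq_len(K))
    data[k, ] <- data[k, ] + amp[k] * sin(2 * pi * 10 * tt + phases[k])
  parcelTimeSeries(data, fs, parcelNames = names(w))
}

#' Generate the full synthetic study
#'
#' Connectome with planted network, parcellation, parcel-level pattern,
#' and case/control seeds -- everything the pipeline stages need.
#'
#' @param cfg a [SynthConfig-class].
#' @param seeds generate seeds too (default TRUE).
#' @return `list(grid, mask, connectome, planted, parcellation, caseSeeds,
#'   controlSeeds)`, with `planted@parcelW` filled in.
#' @export
simulateStudy <- function(cfg, seeds = TRUE) {
  mc <- makeConnectome(cfg)
  parc <- makeParcellation(cfg, mc$planted@grid, mc$planted@brainMask)
  planted <- projectPlanted(mc$planted, parc)
  out <- list(grid = planted@grid, mask = planted@brainMask,
              connectome = mc$connectome, planted = planted,
              parcellation = parc)
  if (seeds) {
    ss <- makeSeeds(cfg, planted)
    out$caseSeeds <- ss$case
    out$controlSeeds <- ss$control
  }
  out
}
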