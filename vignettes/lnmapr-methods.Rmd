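---
title: "Symptom network mapping with lnmapr: models, choices and limits"
author: "lnmapr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom network mapping with lnmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnmapr)
```

## The problem

When a rare symptom — here, autoscopic phenomena such as out-of-body
experiences — is caused by focal brain lesions or elicited by direct
electrical stimulation (DES), the causative sites are typically scattered
across the brain. Lesion network mapping asks what those scattered sites
share: instead of comparing locations, each site is used as a seed in a
large *normative* resting-state connectome, and the symptom is attributed
to the network the seeds have in common. `lnmapr` implements that pipeline
end to end, together with the downstream annotation analyses (cortical
expansion, receptor density and MEG band maps) and a synthetic-data
generator that plants a known network so every stage can be validated
against ground truth.

## The mapping model

For a seed mask $S$ and connectome subject $s$ with voxel time series
$x_v(t)$, the seed time course is the unweighted mean over in-mask seed
voxels. Its Pearson correlation $r_{v,s}$ with every in-brain voxel is
variance-normalized with Fisher's transform, $z = \operatorname{atanh}(r)$,
clipped at $|r| = 1-\varepsilon$ (default $\varepsilon = 10^{-7}$) so
perfect correlations stay finite. Across the $n$ subjects, a one-sample
t statistic per voxel,
$t_v = \bar z_v / (s_{z_v}/\sqrt{n})$ with $n-1$ df, summarizes how
reliably the seed connects to voxel $v$.

Three group-level constructions follow:

* **Sensitivity.** Each case seed's t map is binarized (strictly
  `t > threshold`, positive tail) and the binary maps are overlapped. The
  sensitivity mask keeps voxels present in at least 80% of the case maps.
  The comparison is *inclusive* (`>=`): a voxel shared by 20 of 25 maps is
  exactly 80% and counts as in. With the inclusive rule a 20/25 consensus
  — the natural headline case — is representable; a strict rule would
  silently require 21/25.
* **Specificity.** The unthresholded per-lesion t maps of cases and
  controls are compared voxelwise with a pooled-variance two-sample t
  test, by default one-tailed in the case > control direction (a Welch
  variant and a two-sided option are exposed). Family-wise error is
  controlled by Bonferroni over the in-mask voxels — deliberately
  conservative; random-field and permutation corrections are out of
  scope.
* **Conjunction.** The hub is the voxelwise AND (product) of the
  sensitivity and specificity masks, with both rules recorded verbatim in
  its provenance.

Seeding the hub back through the connectome yields the symptom network
map. The group t map is converted to a standard-normal-equivalent z map by
CDF matching through the one-tailed p value
($z = \Phi^{-1}(P(T_\mathrm{df} \le t))$, computed on the log scale so
large t stays finite and monotone). Transforming a t statistic with
Fisher's r-to-z is not well defined — Fisher's transform applies to
correlations — so CDF matching is the default reading; the per-voxel mean
Fisher-z map is available via `method = "meanz"` for users who prefer the
literal alternative.

### Thresholds are severities, not constants

A fixed cut such as `t > 7` is calibrated to a 1000-subject connectome
(at df = 999 and a ~230,000-voxel 2-mm brain mask it corresponds to a
Bonferroni-corrected one-tailed p below $10^{-6}$; the package's
acceptance script recomputes this). On a 30-subject synthetic connectome
the same t value would be absurdly strict, so `thresholdBinarize()`
accepts either a fixed `tMin` or an `alphaFWE` severity which it converts
to the equivalent one-tailed t quantile at the map's df. All
pipeline-level defaults are expressed as severities (`alphaFWE = 0.05`)
for exactly this reason.

Whether the original `t > 7` cut is one- or two-tailed is not fully
determined by its source; because only positive correlations are
thresholded, the package treats positive-tail thresholding as the
default and records the rule on every binary map.

## Parcel-level spatial correlation

`parcelMeans()` reduces any volumetric map to K per-parcel means
(trilinear resampling to the parcellation grid first when needed; empty
parcels become missing). `spatialCorrelation()` computes Pearson r over
pairwise-complete parcels with a parametric two-tailed p from the t
distribution with $n-2$ df — matching the reporting style the pipeline is
meant to reproduce — and `batchCorrelate()` applies Benjamini–Hochberg FDR
*within one family* of maps (e.g. all 19 receptor maps, or all 6 band
maps). Whether FDR should pool across families is a study-level choice;
the family is therefore an explicit argument, never implicit. Missing
parcels are handled by pairwise deletion with n adjusted in the p value.
A spatial-autocorrelation-preserving null is deliberately not the default:
the hook exists, but the plain parametric p is what the reported numbers
use.

One source ambiguity is worth stating: the descriptive text for the
expansion-map analysis mentions a two-sample t test while reporting
correlation coefficients; `lnmapr` implements those analyses as Pearson
spatial correlations, consistent with every reported r/p pair.

## MEG band analysis

Six canonical bands are built in (delta 2–4, theta 5–7, alpha 8–12,
beta 15–29, low gamma 30–59, high gamma 60–90 Hz). Signals are band-passed
with a zero-phase (forward–backward) 4th-order Butterworth filter,
envelopes are the magnitude of the FFT-based analytic signal, and 5% of
samples are trimmed from each end before any statistic — the analytic
signal is unreliable near the edges, and 5% of a typical 60-second
segment comfortably covers the filter's transient. Amplitude envelope
correlation (AEC) is the Pearson correlation of trimmed envelopes; no
leakage orthogonalization is applied before AEC (none is assumed by the
analyses this package reproduces), and `nodeStrength()` reduces a
connectivity matrix to mean off-diagonal connectivity per parcel.

Both readings of a "band map" are implemented because the source is
genuinely ambiguous: `bandPowerMap()` (mean squared trimmed envelope — the
default, since a pronounced occipital alpha *power* elevation is the
canonical referent) and AEC `nodeStrength()`. The cross-band composite
`compositePC1()` Fisher-transforms each band matrix and takes the first
principal component across bands of the node-strength vectors (PCA over
vectorized matrices is available with `method = "edges"`); the component
sign is fixed to correlate positively with the mean strength map.

## The synthetic study

`synthConfig()` freezes the study conditions; all generators are pure
functions of the config and its master seed, with per-object child
streams so adding one object never perturbs another.

* **Grid and pattern.** 24×28×24 voxels at 2 mm with an ellipsoidal brain
  mask (~4,600 voxels); the planted network W is two Gaussian blobs (5 mm
  sd, amplitudes 1 and 0.9) normalized to max 1. Two blobs make the
  "distributed network" structure nontrivial while keeping the top-decile
  region (~460 voxels) compact.
* **Connectome.** 30 subjects × 200 timepoints:
  $x_{v,t} = W_v\,a_s(t) + \epsilon_{v,t}$ with a unit-variance AR(1)
  latent ($\phi = 0.4$, typical of slow hemodynamic autocorrelation) and
  spatially smoothed Gaussian noise (sd 1, FWHM 4 mm), rescaled exactly in
  Fourier space so the per-voxel noise sd equals the configured value.
  Under this model the expected seed–voxel correlation has the closed form
  $w_1 w_2 / \sqrt{(w_1^2+\sigma^2)(w_2^2+\sigma^2)}$, which the tests
  verify by simulation and which was used to size the defaults: at
  $\sigma = 1$ the suprathreshold region of a strong seed sits near
  $W \gtrsim 0.15$–0.25, so the conjunction hub should bracket the
  top-decile region rather than flood the mask.
* **Seeds.** 25 case seeds centred above the 0.9 weight quantile, 25
  controls below the 0.3 quantile; 24% of each list are 3-mm spheres
  (DES-like, 6 of 25 matching the case mix being emulated), the rest
  irregular blobs grown by a random walk (~15 voxels). Blob growth may
  extend beyond the centre stratum into the upper half of the weight
  distribution — real lesions are not confined to network peaks — and
  centres keep a 2-voxel minimum separation, since causative sites do
  cluster. Seeds never overlap.
* **Annotations.** `makeAnnotation()` mixes the standardized planted
  parcel pattern with independent noise,
  $y = \rho\,\tilde W + \sqrt{1-\rho^2}\,\eta$, so the expected sample
  correlation is the target $\rho$; at K = 100 the sampling sd follows the
  Fisher approximation $(1-\rho^2)/\sqrt{97} \approx 0.07$–0.09.
* **MEG.** 60 s at 250 Hz, parcel k carrying a 10 Hz tone of amplitude
  $0.5 + 1.5\,W_k$ with random phase plus unit-sd white noise: only the
  alpha band inherits the spatial pattern. A numeric check of the
  filters shows out-of-band power leakage of the tone below $10^{-6}$,
  so off-band maps are noise-only by construction.

### What the generator does and does not emulate

It reproduces the *statistical couplings* the pipeline relies on — a
shared spatial pattern across subjects, case seeds on it and controls off
it, annotations with controlled effect sizes, a band-specific oscillatory
signature — at a problem size (full pipeline in roughly a minute on one
CPU) chosen so the whole validation suite runs in minutes. It does not
emulate hemodynamics, head geometry, realistic covariance of resting-state
fMRI, MEG source leakage, or anatomy. Passing recovery tests therefore
demonstrates that the *statistics* do what they claim on data satisfying
their assumptions; they say nothing about the anatomical claims (angular
gyrus, pulvinar) that require the real 1000-subject connectome and curated
clinical lesions, which are explicitly out of scope.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based; world coordinates follow the NIfTI RAS-mm
  affine. `worldToVoxel()` rounds halves away from zero — any fixed rule
  works, but it must be stated, and this one is symmetric about the
  origin.
* Sphere ROIs use inclusive voxel-centre distance (`<= radius`): at 1 mm
  isotropic resolution a 3-mm sphere is exactly the 123 lattice points of
  squared norm ≤ 9. Partial-volume membership is undefined in the source
  description; centre membership is deterministic and oracle-checkable.
* Mask resampling is nearest-neighbour (preserves binarity); continuous
  maps resample trilinearly (preserves smoothness); the two are never
  interchanged.
* Undefined voxels (outside the brain, zero variance, insufficient
  subjects) carry an explicit validity flag and propagate as missing.
  Silent zeros would bias every downstream group statistic.
* Zero group spread with nonzero mean yields a signed infinite t that is
  kept valid (a strict threshold passes it); zero spread with zero mean is
  flagged undefined.
* The Fisher clip $\varepsilon = 10^{-7}$ bounds |z| at about 8.4,
  far above any value group statistics meaningfully distinguish.
* Peak detection uses 26-connectivity components; ties at a component
  maximum resolve to the lexicographically smallest voxel index so the
  output is fully deterministic.

## Known limitations

* Bonferroni FWE is conservative for spatially smooth maps; cluster-level
  and permutation inference are out of scope.
* The parametric p in `spatialCorrelation()` ignores spatial
  autocorrelation between parcels, as do the numbers it is designed to
  reproduce; treat parcel-level p values accordingly.
* The connectome storage model is in-memory and masked; a loader adapter
  (`subjectTimeSeries()` from any backing store) is the extension point
  for real datasets, which are not downloaded or handled at full scale.
* `compositePC1()` on strength vectors discards edge-level structure; the
  `"edges"` variant retains it at higher cost, and the choice is exposed
  because the source description is ambiguous.
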