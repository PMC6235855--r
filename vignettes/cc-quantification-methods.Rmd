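---
title: "Quantifying the choriocapillaris from repeated OCTA scans: methods and design"
author: "ccquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the choriocapillaris from repeated OCTA scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccquant)
```

## The problem

The choriocapillaris (CC) is the dense capillary monolayer of the inner
choroid. On commercial swept-source OCT angiography (SS-OCTA), a single en
face image of the CC slab is dominated by multiplicative speckle: the
capillary mesh, whose mean intercapillary distance (ICD) is on the order of
20-27 µm, sits at or below the lateral sampling limit (10 µm/pixel for a
3 mm x 3 mm, 300-line protocol), and flow deficits (FDs) - dark regions
without detectable flow - are easily confused with noise. `ccquant`
implements a complete quantification chain for this setting:

1. register repeated scans of one location to the first scan
   (translation -> affine -> cubic B-spline) and average them;
2. track image quality across cumulative averages (global entropy, global
   standard deviation, local texture correlation, PSNR);
3. estimate the mean ICD from the radially averaged 2-D power spectrum of a
   region;
4. segment FDs by fuzzy c-means (FCM) over pixel intensities, with the
   cluster count chosen by an explained-variance elbow rule;
5. quantify the FD population by five indices - density (FDD), number
   (FDN), mean size (FDS), aspect-ratio index (FDARI), complexity index
   (FDCI) - plus six functional maps.

Because no reference data ship with the package, a synthetic phantom
generator with complete ground truth (known spacing, known motion, known
speckle statistics, planted deficits) makes every stage testable.

## Registration model

All three stages minimize the same cost, the negative mutual information
(MI) of the joint intensity histogram between the fixed image $I_F$ (scan 1)
and the resampled moving image $I_M \circ T_\mu$:

$$\hat T = \arg\min_\mu \; C(T_\mu; I_F, I_M), \qquad C = -\,I(I_F;\, I_M \circ T_\mu),$$

with $I(A;B) = H(A) + H(B) - H(A,B)$ estimated from a 32 x 32-bin joint
histogram over the fixed [0, 255] intensity range. The transform is
parameterised as $T(p) = A(p - c) + c + b + d(p)$: a 2 x 2 matrix $A$ about
the image centre $c$, an offset $b$, and a cubic B-spline free-form
displacement field $d$ on a regular control lattice (default spacing 32 px,
displacement cap 2 x spacing to prevent folding).

Numerical choices that mattered in practice:

* **Partial-volume (PV) histogram accumulation** for all continuous
  parameters. Interpolating intensities before binning smooths speckle and
  biases MI maxima toward half-pixel offsets; PV accumulation avoids that
  but is itself attracted to integer-grid coincidences. The translation
  stage therefore refines subpixel shifts by parabolic interpolation of the
  integer-shift MI surface, which needs no interpolation at all.
* **Search on lightly smoothed copies** (Gaussian, sigma = 1 px). At the
  speckle levels the generator emulates (about 2 looks), the raw-image MI of
  a correctly aligned pair is comparable to the finite-sample MI bias floor;
  light smoothing lifts the alignment signal an order of magnitude above
  that floor without displacing the optimum. Recorded stagewise costs and
  the stage-acceptance guards always use the raw images.
* **Stage guards.** A stage that fails to lower the raw-image cost is
  reverted and flagged (`affine-no-gain`, `bspline-no-gain`), so the
  stagewise cost sequence is non-increasing by construction. A pair whose
  best alignment stays below 1.8 x the median MI of deliberately misaligned
  probes is flagged `no-signal` and excluded from averaging; later stages
  clear the flag if they restore the signal.
* **B-spline optimization** is coordinate descent over control points with
  a descending step schedule (4, 2, 1, 0.5, 0.25 px), each move scored by
  local MI over the node's support window (16-bin histograms - finer
  binning puts the small-sample MI bias above the signal). A global MI check
  accepts, scales back, or rejects the whole field. This deterministic
  scheme replaced a stochastic gradient ascent on MI, which is hard to make
  both reproducible and fast in pure R; the objective is unchanged.

Averaging is the pixelwise arithmetic mean over each pixel's *valid*
contributors: pixels that a fitted transform maps from outside the moving
image's domain are masked out rather than zero-filled, which avoids rim
artifacts. Scan 1 is always the reference, so every pixel has at least one
contributor.

## Quality metrics

Global entropy is the Shannon entropy of the 256-level histogram divided by
8 bits, so it lies in [0, 1]; global standard deviation is the population SD
on the [0, 255] scale. Local texture correlation tiles the image into
32 x 32-px blocks and averages the gray-level co-occurrence correlation
(distance 1, four directions, 32 levels, symmetric counts); an all-constant
block contributes 1 by convention. PSNR is $10\log_{10}(255^2/\mathrm{MSE})$
against the full-stack average, with `Inf` as the identical-image sentinel.
On synthetic repeats, std and entropy fall monotonically with the number
averaged while texture correlation and PSNR rise - the expected signature of
speckle suppression by incoherent averaging (RMS error against the clean
scene tracks $1/\sqrt{k}$ for rigid motion).

## ICD from the radial power spectrum

A square region (the protocol uses 650 µm x 650 µm, i.e. 65 px) is
mean-subtracted, Hann-windowed (without windowing, spectral leakage of the
DC pedestal masks the capillary ring at such small regions), Fourier
transformed, and the squared magnitude averaged over annuli one frequency
sample wide. The quasi-periodic mesh produces a "cusp": after a
running-median detrend in log power, the most prominent local maximum
within the physiologic spacing band (default 15-60 µm, intersected with the
Nyquist limit) is taken, and its reciprocal frequency is the ICD. Reported
precision is one frequency bin (+/- ~2 µm at 65 px and 10 µm/px). Band-edge
bins are eligible peaks with one-sided curvature: a 20 µm spacing at
10 µm/px sits exactly at Nyquist and its ring falls into the last annulus.
If no peak clears a prominence floor (5 % of the in-band detrended range),
the function refuses to report a value - unreliable CC texture should fail
loudly, not silently.

## FD segmentation

FCM runs on the one-dimensional pixel-intensity feature with fuzzifier
m = 2, tolerance 1e-5 on membership change, at most 300 iterations, and
deterministic centroid initialization at evenly spaced intensity quantiles
(an empty cluster is re-seeded once from a seeded uniform draw). Centroids
are sorted ascending and memberships permuted to match, which makes the map
invariant to cluster relabelling. The elbow rule grows k until the
between-cluster variance of the hard partition explains at least 99 % of
the total intensity variance (k = 1 with a warning on constant images;
kMax with a warning if the threshold is never reached). The FD map is the
*first membership* - the cluster with the lowest centroid - since deficits
are the darkest structures in en face CC OCTA. The pipeline normalizes
illumination (division by a Gaussian background estimate, default scale
200 µm) before clustering, so shading cannot masquerade as deficit.
Spatially regularized FCM variants are deliberately out of scope; the
intensity-only model keeps the segmentation auditable.

Projection artifacts - retinal-vessel flow imprinted on the CC slab - are
removed by exclusion against a caller-supplied binary retinal-vessel mask:
any FD component with at least 50 % (configurable) of its pixels under the
mask is dropped. Generating the retinal-vessel mask is out of scope.

## Morphometric indices

With $A_i$, $P_i$, $M_i$, $N_i$ the area, perimeter and ellipse axes of FD
component $i$ (x components in total, 8-connectivity by default):

$$\mathrm{FDD} = \frac{\sum \text{FD pixels}}{\text{all pixels}},\quad
\mathrm{FDN} = x,\quad
\mathrm{FDS} = \frac{\sum_i A_i}{x},\quad
\mathrm{FDARI} = \frac{1}{x}\sum_i \frac{M_i}{N_i},\quad
\mathrm{FDCI} = \frac{1}{x}\sum_i \frac{P_i^2}{4\pi A_i}.$$

The perimeter is the 8-connected boundary chain length (unit steps 1,
diagonal steps $\sqrt2$; an isolated pixel counts 4 pixel-units). This
estimator keeps FDCI of large rasterized disks near 1 - the isoperimetric
normalization intends a disk to score 1 - whereas pixel-edge counting would
bias disks to ~1.27. Measured on rasterized disks of radius 10-14 px the
index is 1.07-1.09 (digitization fluctuates by a few percent with radius).
Axes come from the moments-equivalent ellipse (second central moments with
the 1/12 pixel-spread correction; a single pixel gets both axes equal to
one pixel). Skeleton ("centre length") maps use Zhang-Suen thinning, with
per-component length the spanning-tree length of the 8-adjacent skeleton
pixels. FDD, FDN, FDARI and FDCI are invariant to the physical pixel size;
FDS scales with pixel area. No minimum-size filter is applied by default;
border-touching components are retained.

## The synthetic phantom

The generator emulates exactly the study conditions the pipeline is meant
for. The capillary pattern is the complement of soft septal gaps placed on
a jittered hexagonal lattice whose *row spacing equals the requested ICD*
(point spacing $2/\sqrt3 \cdot$ ICD), so the first ring of the power
spectrum falls at 1/ICD; gaps are rendered at subpixel accuracy because
integer-rounded placement phase-jitters the lattice enough to erase the
ring at the 2-pixel resolvability limit. Default contrasts are vessel 100,
septa 45, planted FD 10 gray levels: dim enough that 2-look speckle rarely
clips at 255 (clipping piles mass at the top gray level and inverts the
entropy-vs-averaging trend), with an FD-to-septa gap of about 3.7 standard
deviations of the 5-average speckle so the darkest FCM cluster isolates the
planted deficits. The "lobular" variant keeps the same lattice periodicity
(the spectral contract pins the dominant peak at 1/ICD) but widens the dark
gaps and brightens feeder sites. Speckle is multiplicative
Gamma(shape = looks, mean = 1) noise - the standard multi-look surrogate,
CV $= 1/\sqrt{\text{looks}}$; the default study condition is looks = 2,
an aggressively noisy single scan. Motion ground truth reuses the
registration module's own transform representation, so
`registerThreeStep(img, applyTransform(img, t))` recovers $t^{-1}$ by
construction of the resampling convention. Planted deficits are
non-overlapping ellipses with exponentially distributed areas
(mean 1500 µm²), controllable elongation, and an exact truth mask whose
indices are computed through the morphometrics module at construction.

What the phantom does **not** emulate: coherent PSF structure, RPE
shadowing, flow decorrelation statistics, B-scan-wise motion artifacts, or
eccentricity gradients within one image. Passing tests therefore certify
the algorithmic chain against known truth, not clinical performance.

## Problem sizes and determinism

The test suite and the acceptance script run on 256 x 256-px scenes
(2.56 mm at 10 µm/px) with 5 repeats at looks = 2, 65-px ICD regions, and
smaller scenes for plumbing checks - sizes chosen so the full suite
completes in minutes on one CPU while every tolerance stays attributable
to the method rather than to sampling noise. All stochastic steps
(pattern jitter, speckle, deficit placement, mixture draws) are seeded;
pipeline reports contain no timestamps, so identical inputs, configuration
and seeds give byte-identical CSV/JSON reports (timestamps go to the run
log). Registration itself is deterministic: integer searches, Nelder-Mead
with fixed starts, and coordinate descent in fixed node order.

## Known limitations

* Rotation/scale capture range of the affine stage is set by its coarse
  sweep (+/- 5 deg, scale 0.97-1.03); larger distortions need a better
  initialization.
* The elbow rule on continuous speckled intensity distributions tends to
  saturate at `kMax` (the 99 % target is demanding); the FD map is robust
  to this because only the darkest cluster is extracted, but reported k
  should be read with that in mind.
* ICD precision is one radial-frequency bin; spacings at the Nyquist limit
  (2 px) are reported from the band-edge bin and are upper-bounded by it.
* FDCI of compact deficits carries the few-percent digitization bias of the
  chain-length perimeter; comparisons across images at the same pixel size
  are unaffected.
* Per-pixel/local ICD maps, eccentricity fits, spatially constrained FCM,
  and volumetric (3-D) registration are out of scope.
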