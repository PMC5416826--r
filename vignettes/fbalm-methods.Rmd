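---
title: "Models and methods behind the fbalm pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the fbalm pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific models, the numerical choices and
the deliberate design decisions inside `fbalm`, in the spirit of the
methods sections of the established omics/imaging packages. Nothing here
states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The imaging model

Binding-activated localization microscopy (BALM) of DNA, in its
structure-fluctuation-assisted variant (fBALM), produces movies in which
a DNA dye (e.g. YOYO-1) transiently binds renaturing double-stranded DNA
and emits a burst of fluorescence until it dissociates or bleaches.
Because only the bound dye is appreciably fluorescent, each frame shows
a sparse set of diffraction-limited spots over a smooth background, and
standard single-molecule localization recovers emitter positions far
below the diffraction limit.

### Blinking kinetics

The literature describes the binding mechanism qualitatively, not
kinetically, so the simulator adopts the simplest memoryless model
consistent with transient binding:

* new binding events per frame: Poisson with mean
  `mean_events_per_frame` (default 8), each at a site drawn uniformly
  from the ground-truth structure;
* on-time: geometric with mean `mean_on_frames` (default 3 frames),
  occupying strictly consecutive frames — no within-event dark gaps, so
  the consecutive-frame merging stage has an unambiguous ground truth;
* photons per event-frame: Poisson with mean `photons_per_frame_mean`
  (default 1000 detected photons).

There is no quantitative published photon budget or on-time for YOYO-1
bursts under these conditions; all three rates are free, configurable
parameters, and the defaults were chosen once as values typical of
intercalator-based SMLM at moderate excitation (one to a few thousand
detected photons per burst, on-times of a few tens of milliseconds at
20 ms frames).

### Chromatin ground truth

fBALM images of cardiomyocyte nuclei show a "spider's web": dense
chromatin clusters of 100–400 nm diameter at the intersections of a
filamentous network, separated by DNA-sparse voids of similar size. The
generator reproduces exactly these features and no more:

* cluster centres uniform in the nuclear ellipse (with a margin keeping
  whole clusters inside), diameters uniform in `[100, 400]` nm;
* a cluster's diameter is read as the full extent of its site blob:
  sites are Gaussian about the centre with `sd = diameter/4`, truncated
  at `diameter/2`;
* each centre is connected to its up-to-three nearest neighbours by
  jittered polylines carrying a configurable fraction (default 30%) of
  the sites — cosmetic beyond cluster/void statistics;
* every site lies inside the nuclear boundary (rejection sampling), so
  structural confinement is exact by construction.

What the generator does **not** emulate: nucleosome-scale substructure,
chromatin mobility, dye specificity artifacts, out-of-focus light from
3D structure, and sample drift. Passing tests therefore demonstrate
correctness of the *analysis chain* under a faithful-but-idealized
image-formation model, not performance on any particular real dataset.

### Camera model

Expected photons per pixel are the sum of the Poisson background
(default 10 photons/pixel) and each active event's photons spread by a
pixel-integrated isotropic 2D Gaussian PSF (erf differences;
`psf_sigma_nm = 130` at 100 nm pixels, a typical high-NA widefield
PSF). Per-pixel counts are
`round(offset + gain × Poisson(expected) + N(0, read_noise_sd))`,
clipped to the 16-bit range — a deliberately generic CCD model
(offset 100, gain 1, read noise 2 counts by default). A PSF sigma below
0.25 pixel triggers an undersampling warning.

## Localization

Per frame:

1. **Background**: an 11×11 spatial median filter (robust to the sparse
   emitters themselves); **noise SD**: scaled MAD of the residuals.
2. **Detection**: the classic fBALM rule is that a signal's peak
   intensity must exceed three noise standard deviations above
   background. Applied to raw pixels alone this rule cannot separate genuine PSF-shaped peaks from
   single-pixel shot-noise excursions on a Poisson background (the
   measured false rate is several per 10⁴ pixel-frames). Candidates are
   therefore strict 8-neighbourhood local maxima of the PSF-matched
   Gaussian-filtered, background-subtracted frame exceeding `k = 3`
   noise SDs *of the filtered image*, which must additionally pass the
   raw-pixel rule, and — after fitting — have a fitted peak amplitude
   (`photons·gain / 2πσ²`) above `k` noise SDs. With all three
   conditions the measured false-positive rate on pure-background
   movies is ≈ 0 per 10⁴ pixel-frames while recall on bright isolated
   emitters is ≥ 0.99. `detect_peaks()` itself retains the plain
   "value > background + k·SD and strict local maximum" contract, so
   the threshold arithmetic stays sharp and testable.
3. **Fitting**: background-subtracted centre of gravity in a 7×7 ROI
   with negative-pixel clamping, the approach also used for the 3D foci
   (and by speed-oriented SMLM software); sub-pixel positions, photons
   = ROI sum / gain, and the "signal diameter" operationalized as the
   intensity-weighted radial SD converted to a per-axis Gaussian sigma.
   Candidates whose ROI leaves the frame are dropped and logged, not
   padded.
4. **Precision**: the Thompson–Larson–Webb formula
   `σ_loc² = (σ² + a²/12)/N + 8πσ⁴b²/(a²N²)` — the community standard
   for centroid-class fitters (the original analysis software is cited
   without formulas).

Then, per movie:

5. **Diameter filter**: the broadest ~30% of signals are removed; the
   kept set is `sigma ≤` the `ceil(0.7 n)`-th smallest sigma, ties kept,
   so retention is exactly `ceil(0.7 n)` for distinct sigmas.
6. **Merging**: localizations in strictly consecutive frames closer
   than `2 × mean precision` (recomputed from the table, per-table, not
   per-cell — the finer-grained choice is not documented anywhere)
   are linked greedily, nearest pair first, each row linking to at most
   one partner per side; maximal chains collapse to photon-weighted
   positions with summed photons and recomputed precision. Zero gap
   tolerance is the literal reading of "subsequent frames".

Coordinates are nm with the origin at the outer corner of pixel (1,1)
and pixel centres at `(i − 0.5)·a`; frames are 1-based, matching both R
convention and the ThunderSTORM table dialect accepted by the reader.

## Rendering

* **Histogram mode**: half-open `[k·bin, (k+1)·bin)` binning; the image
  sum equals the rendered localization count exactly at any bin size.
  The chromatin density analysis uses 60 nm bins; final display
  reconstructions use 5 nm pixels.
* **Voronoi mode**: each localization's planar Voronoi ("Wigner–Seitz")
  cell gets the value `1/area` — no single convention for the rendered
  value exists, and inverse area is the standard local-density choice
  that also makes mass conservation testable (∑ value × pixel area ≈ count).
  Cells are clipped to the convex hull of the points dilated by the
  mean nearest-neighbour distance (edge-offset with miter joins):
  unbounded boundary cells would otherwise dominate, and the dilation
  radius keeps them finite without inventing structure. Cell areas are
  computed exactly by incremental bisector clipping (nearest sites
  first, with an early exit once no farther site can cut the cell);
  rasterization assigns each pixel to its nearest site, ties to the
  lowest site index — deterministic and matched by the brute-force
  oracle in the tests.

## Resolution estimation

**Fourier ring correlation.** The localization set is split into
halves — by frame parity by default (deterministic; a merged burst goes
wholly to the half of its first frame), or 50/50 at random under a
seed. Note the caveat: merging joins consecutive frames, so any residual
multi-frame structure can still correlate parity halves; both split
modes are provided and the choice is reported rather than guessed. The
halves are rendered as 10 nm histograms on a common extent, and per
one-Fourier-pixel ring
`FRC(q) = Σ Re(F₁F̄₂) / sqrt(Σ|F₁|² Σ|F₂|²)`, DC excluded, empty rings
undefined. The resolution is `1/q*` where an order-8 least-squares
polynomial (fit on defined rings, frequencies rescaled to `[0,1]` for
conditioning) first descends through the `1/7` threshold — the standard
SMLM criterion; the exact threshold and fit order of the original
analysis are unpublished, so both are configurable. If the polynomial
never crosses, the raw curve's first crossing (linear interpolation) is
used; if nothing crosses, the result is reported as unresolved at the
frequencies examined rather than extrapolated.

**Line profiles.** Intensity profiles are sampled by bilinear
interpolation at half-pixel steps (optionally averaged across a
perpendicular width) and fit with a sum of Gaussians plus constant
baseline by Levenberg–Marquardt, seeded at the largest local maxima;
FWHM = `2·sqrt(2 ln 2)·σ` exactly.

## Chromatin density statistics

Localizations are counted in 60×60 nm² grid squares; only occupied
squares enter the statistics (structural zeros outside the nucleus would
otherwise dominate every moment). Reported per cell: median and mean
counts per square, the **normalized median** — defined here as
median/mean, a dimensionless choice comparable across cells with
different totals; the normalization used originally is not specified —
and the biased moment skewness `g1 = m₃/m₂^{3/2}` ("asymmetry of the
data around the sample mean"; no small-sample correction), defined as 0
when all counts are equal. Cumulative distributions are empirical step
curves whose increments equal the histogram frequencies exactly.
Condition comparison reports per-group mean ± SD of both metrics with
the per-cell scatter, and the direction of the shift; no hypothesis
testing, matching the descriptive original analysis. Conventional-image
intensity histograms run through the same statistics with an intensity
floor (default 50) that removes the low-value background peak outside
the nucleus.

A caution encoded in the tests: a *single* transfer of one signal from a
poorer to a richer square can lower `g1` (the variance in the
denominator grows too); condensation raises skewness in expectation and
under sustained transfers, and that is the property asserted.

## 3D foci morphometry

Point-like nuclear reference foci (e.g. EdU-labelled replication sites)
are detected in 3D stacks as 26-neighbourhood local maxima of a
Gaussian-smoothed stack above `median + k·MAD` (robust statistics, so
the sparse foci themselves do not inflate the threshold; default
`k = 4`), with a brighter-wins minimum separation of one ROI width.
Sub-voxel positions come from a background-subtracted (ROI-minimum
baseline), clamped, intensity-weighted 3D centroid; anisotropic voxels
are converted to nm before any geometry, with the axial PSF defaulting
to 3× the lateral. Deconvolution is out of scope: detection operates on
raw or pre-deconvolved stacks supplied by the caller.

Nearest-neighbour distances are exact Euclidean 3D distances (blocked
O(n²), verified against exhaustive search). Nuclear volume defaults to
the 3D convex hull of the foci — self-contained, noise-robust, and
*exactly* scale-equivariant, so an isotropic contraction by `s` changes
the measured volume by `s³` to machine precision; a voxel-mask
thresholding alternative is provided since the original volume method is
unnamed. The hull is built by a dedicated incremental algorithm with a
length-scaled coplanarity tolerance and is tested against an independent
reference implementation to nine digits. Note that the hull of `n`
uniform interior points *under-covers* a smooth body by ~`n^{-2/3}`
(about 9% at n = 2000, 3.5% at n = 8000); before/after volume *ratios*
cancel most of this deficit, which is why the contraction-recovery test
succeeds within ±3 percentage points even at realistic detection
losses. Before/after comparison reports `Δ<D>` (nm), the normalized
volume change (%), and both foci counts — detection losses thin the
set and bias `Δ<D>` upward, which the tests assert as a direction.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; the pipeline driver derives per-stage seeds from one
global seed and records them in a YAML manifest, so a saved resolved
configuration replays bit-exactly. Unknown configuration keys are
rejected rather than ignored.

The test suite exercises the full chain at reduced problem sizes chosen
to keep each property measurable: a 6.4 × 6.4 µm quarter-scale movie
(4000 frames, ~10⁴ localizations) for the FRC acceptance check, ~350
frames of isolated emitters for accuracy/recall, and 1200 foci for the
contraction recovery. `scripts/acceptance.R` runs the full
experiment-scale configuration (12.8 × 12.8 µm, 15,000 frames, ~10⁵
localizations).

## Known limitations

* No multi-emitter fitting: overlapping PSFs within a frame merge or
  are suppressed, which at high event rates biases density statistics.
* No drift simulation or correction (not part of the original
  analysis).
* The FRC parity split can retain correlation from merged multi-frame
  bursts (documented above; both split modes available).
* 2D localization only; the 3D morphometry path is for confocal foci
  stacks, not astigmatic SMLM.
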