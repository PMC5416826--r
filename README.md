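# fbalm

Simulation and analysis of **binding-activated localization microscopy
(BALM / fBALM)** experiments on nuclear chromatin, as an R package.

In fBALM, a DNA dye such as YOYO-1 binds transiently to locally
renaturing double-stranded DNA; only the bound dye fluoresces, so a
widefield movie shows sparse diffraction-limited bursts that can be
localized far below the diffraction limit and accumulated into a
super-resolution map of nuclear DNA density. This package provides the
complete computational chain around such experiments for people who
want to benchmark, reproduce or reuse the analysis without access to
raw acquisitions:

* a **simulator** of clustered "spider-web" chromatin ground truths
  (cluster diameters 100–400 nm separated by DNA-sparse voids inside an
  elliptical nucleus), of blinking movies with a full camera model
  (Poisson binding events, geometric on-times, Poisson photons,
  pixel-integrated Gaussian PSF, Poisson background, Gaussian read
  noise, offset/gain), and of 3D confocal stacks of point-like nuclear
  foci;
* a **localizer**: per-frame median background and MAD noise
  estimation, peak detection at *k* = 3 noise SDs above background,
  centre-of-gravity sub-pixel fitting, Thompson–Larson–Webb precision

  σ²loc = (σ² + a²/12)/N + 8πσ⁴b²/(a²N²),

  removal of the ~30% broadest signals by fitted PSF diameter, and
  merging of localizations appearing in consecutive frames closer than
  2× the mean localization precision;
* **renderers**: binned histogram images (count-conserving) and Voronoi
  ("Wigner–Seitz") cell density images at 5 nm pixels, with exact cell
  areas and an oracle-matched rasterizer;
* **resolution estimation**: Fourier ring correlation between
  half-dataset reconstructions with a polynomial fit crossing the 1/7
  threshold, and multi-Gaussian line-profile FWHM fitting;
* **chromatin density statistics**: signals per 60×60 nm² grid square,
  per-cell skewness g₁ and normalized median (median/mean), cumulative
  curves, and between-condition comparisons (e.g. untreated vs.
  ischemia-like);
* **3D foci morphometry**: detection and 3D centre-of-gravity
  localization of fluorescent foci, nearest-neighbour distance
  distributions, convex-hull nuclear volumes, and before/after change
  summaries (Δ⟨D⟩ in nm, volume change in %);
* a **pipeline driver** (`run_pipeline()`) with strict YAML
  configuration, derived per-stage seeds, a replayable manifest, and
  CSV/TIFF/YAML interchange formats (ThunderSTORM-dialect localization
  tables are read transparently), plus a thin command-line wrapper in
  `inst/cli/fbalm.R`.

## A worked example

Simulate a quarter-scale fBALM experiment, localize it, and measure the
reconstruction's resolution:

```r
library(fbalm)

gt <- generate_chromatin_structure(chromatin_params(
  nucleus_center = c(3200, 3200), nucleus_semiaxes = c(2900, 2500),
  n_clusters = 30, n_sites = 10000), seed = 7)

sim <- simulate_movie(gt, acquisition_params(
  n_frames = 4000, mean_events_per_frame = 2,
  photons_per_frame_mean = 1000, background_photons_per_pixel = 10,
  read_noise_sd = 2, fov_px = c(64, 64)), seed = 8)

tab <- localize_movie(sim$movie, verbose = TRUE)
#> detected: 18313 raw localizations in 4000 frames
#> diameter filter: kept 12820/18313 (70.0%)
#> merge: 12820 -> 9900 localizations (radius 11.14 nm)

print(tab)
#> Localization table: 9900 localizations, 3997 frames,
#>   mean precision 5.57 nm (pixel 100 nm)

r <- frc_resolution(tab, render_pixel_nm = 10)
print(r$resolution)
#> FRC resolution: 38.8 nm (threshold 0.1429, fit crossing)
```

Reading the output: 4000 frames at 2 binding events per frame produced
~18k raw detections; the diameter filter removed the broadest 30%;
merging collapsed multi-frame bursts into ~10k signals with ~5.6 nm
estimated precision. Splitting those signals into frame-parity halves,
rendering both at 10 nm and correlating them per Fourier ring gives a
resolution of ~39 nm at the 1/7 threshold — a number of the same order
as published fBALM reconstructions of whole nuclei.

The 3D morphometry path works the same way:

```r
before <- generate_foci_3d(1200, seed = 21)
after  <- apply_isotropic_contraction(before, 0.8434)  # -40% volume
compare_before_after(before, after)
#> Structural change: delta <D> = -47.4 nm (302.9 -> 255.4 nm),
#>   volume change = -40.0% (149.46 -> 89.67 um^3), n = 1200 -> 1200 foci
```

The −40.0% volume change is exact for any noiseless contraction by
0.8434 (the cube law); the ~−47 nm shortening of the mean
nearest-neighbour distance scales with the foci density.

## Documentation

The methods vignette (`vignettes/fbalm-methods.Rmd`) describes the
kinetic and camera models, every analysis rule and its rationale, the
numerical choices (tolerances, tie-breaks, degenerate inputs), what the
synthetic data do and do not emulate, and known limitations.
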