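# fibis

Single-mitochondrion metabolic imaging from label-free NADH
fluorescence-lifetime microscopy (FLIM).

The metabolic co-factor NADH is autofluorescent, with a short fluorescence
lifetime (~0.4 ns) when free in the cytosol and a long lifetime (~3.4 ns)
when protein-bound, so the per-pixel decay reports the glycolytic vs
oxidative (OXPHOS) balance without any staining. Resolving this signal for
*individual mitochondria* in live cells is hard: time-correlated
single-photon counting (TCSPC) needs many accumulated scan frames, and over
those frames mitochondria move (motion blur), laser scanning adds periodic
line noise, and diffuse cytosolic NADH buries the structures of interest.

`fibis` implements FIBIS — FLIM intensity-based image segmentation — an
algorithm that isolates single mitochondria from accumulated NADH intensity
despite these degradations, together with the phasor-FLIM machinery needed
to turn each segmented mitochondrion into a metabolic index, the
image-quality metrics used to benchmark the segmentation, and a synthetic
TCSPC acquisition generator so the whole method is testable without
microscope data.

## The method

**Phasor transform.** Each pixel's photon arrival-time histogram
h(t_k) over one laser period T is mapped, fit-free, to first-harmonic
Fourier coordinates

    g = Σ_k h_k cos(ω t_k) / Σ_k h_k,   s = Σ_k h_k sin(ω t_k) / Σ_k h_k

with ω = 2π/T (80 MHz repetition by default). Mono-exponential decays of
lifetime τ land on the *universal semicircle* at
g = 1/(1+(ωτ)²), s = ωτ/(1+(ωτ)²); mixtures land inside it, on chords.
Instrument response is removed by a single complex calibration factor
measured on a reference fluorophore of known lifetime (Coumarin 6, τ =
2.5 ns): `calibrate()` multiplies every pixel's z = g + i·s by
z_expected/z_measured.

**FIBIS segmentation** (`fibis_pipeline()`), in order:

1. `normalize_frames()` — each scan frame is z-scored so faint frames
   contribute equally, the frames are averaged, and the average is min-max
   rescaled to [0, 1];
2. `detect_scan_noise()` / `fft_denoise()` — periodic scan-line noise is
   detected as outlier peaks (median + 6·MAD against same-radius
   components) on the stripe axis of the centred 2-D Fourier magnitude and
   suppressed with Gaussian notches;
3. `iqr_otsu_threshold()` — Otsu's threshold computed on the
   interquartile-restricted intensity histogram (so a few very bright
   pixels cannot stretch the histogram), applied to the full image;
4. `size_filter_erode()` — 8-connected components outside a mitochondrial
   size range (0.5–7 µm equivalent diameter; elongation counts against the
   upper limit) are deleted if too small or iteratively eroded if too
   large, removing boundary pixels below the component's median intensity
   so erosion follows the intensity gradient of motion-blur trails.

**Metabolic index.** `object_phasor()` aggregates each object's
intensity-weighted mean phasor; `fb_fraction()` projects it onto the chord
between the pure free (0.4 ns) and pure bound (3.4 ns) NADH phasors and
returns the bound fraction in [0, 1] (higher = more OXPHOS-like).
Per-condition clouds are gated with a 95% Mahalanobis ellipse
(`ellipse_outlier_filter()`) and compared with a two-sample
Kolmogorov–Smirnov test (`group_compare()`).

**Benchmarking.** `benchmark_similarity()` scores FIBIS masks and a
0.9-quantile-normalized raw-intensity Otsu baseline
(`baseline_raw_threshold()`) against ground truth with MSE, PSNR, SSIM and
multi-scale SSIM (`mse()`, `psnr()`, `ssim()`, `ms_ssim()`), reporting
per-trial rows and mean relative improvements.

**Synthetic acquisitions.** `make_scene()` / `render_stack()` generate
256×256 px, 15-frame, 256-bin TCSPC stacks at 80 MHz: ellipse/capsule
mitochondria with known bound fractions, Poisson photon statistics, exact
photon conservation between frames and the accumulated decay, linear
per-frame drift, multiplicative stripe noise and a diffuse cytosolic
background — with ground-truth masks and per-object tables.

## Worked example

```r
library(fibis)

scene <- make_scene("paper_benchmark", seed = 7)   # blur + stripes + background
acq   <- render_stack(scene)
mask  <- fibis_pipeline(acq$stack)
mask
#> <fibis_mask> 9 object(s) in 256 x 256 px (8-connected, 0.2 um/px)
#>   equivalent diameter: 1.22-3.60 um; total area 1124 px

bundle <- field_phasor(acq$stack)
bundle$meta$calibrated <- TRUE   # synthetic decays carry no instrument response
records <- mitochondrion_records(mask, bundle, group = "demo")
head(records[, c("id", "size_um", "g_mean", "s_mean", "fb_fraction")], 3)
#>   id  size_um    g_mean    s_mean fb_fraction
#> 1  1 1.611648 0.5112848 0.3482277   0.6372809
#> 2  2 2.068353 0.6895380 0.2880458   0.3852977
#> 3  3 2.827710 0.7986761 0.2490833   0.2300968
```

The scene truly contains 9 mitochondria; FIBIS recovers all 9. Each row is
one mitochondrion: its equivalent diameter in µm, its mean phasor
coordinates, and its bound-NADH fraction (object 1 sits 64% of the way
toward the pure-bound endpoint — relatively OXPHOS-shifted; object 3 is
glycolysis-shifted). Comparing two groups of fractions:

```r
group_compare(records$fb_fraction, other_condition$fb_fraction)
#> <group_compare> two-sample KS: D = 0.6667, p = 0.0336 (n = 9 vs 9)
```

A command-line wrapper (`inst/exec/fibis`) exposes the same pipeline as
`simulate`, `phasor`, `calibrate`, `segment`, `fraction`, `compare` and
`benchmark` subcommands; every run writes a JSON provenance record next to
its outputs.

## File formats

- **TCSPC stacks**: multipage 16-bit TIFF (F intensity frames followed by T
  decay planes) plus a JSON sidecar (`rep_rate_hz`, `pixel_size_um`, `F`,
  `T`); lossless for counts up to 65535.
- **Phasor bundles**: a self-describing single-file named-array container
  (ASCII magic `FIBISPB1`, JSON header with dataset names/dims and
  metadata, float64 little-endian payloads for `g`, `s`, `intensity`) —
  an open stand-in for proprietary phasor file formats.
- **Object tables**: CSV with fixed columns `id, group, area_px, size_um,
  centroid_y, centroid_x, g_mean, s_mean, fb_fraction, outlier_flag`.

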