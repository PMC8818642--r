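---
title: "Superresolution and AFM morphometrics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superresolution and AFM morphometrics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanometrics)
```

This vignette documents how each analysis in `nanometrics` works and why it
is built the way it is. Every pipeline is exercised here on small seeded
synthetic scenes whose ground truth is known, which is also how the test
suite validates parameter recovery.

## Localization tables and rendering

Single-molecule localization microscopy produces event tables — one row per
detected fluorophore blink with coordinates in nm, the camera frame, and a
per-event localization precision. `loc_table()` validates such tables,
`filter_by_precision()` keeps only events with precision strictly below a
cutoff (40 nm by default), and `render_image()` accumulates events into a
pixel grid (20 nm pixels by default) in count mode with half-open pixel
intervals, so an event on a boundary lands in exactly one pixel.

```{r render}
tab <- loc_table(frame = c(1L, 1L, 2L), x_nm = c(25, 45, 301),
                 y_nm = c(12, 31, 44), precision_nm = c(9, 14, 22))
img <- render_image(tab, pixel_size_nm = 20)
dim(img$pixels)
```

## Bundle width measurement

The width of a filament bundle is measured from the localizations
themselves, not from a rendered image, in five stages
(`measure_bundle_width()` runs them all):

1. **Orientation** — `fit_orientation()` fits a total-least-squares line
   (first principal direction) through the localization cloud. TLS rather
   than ordinary regression because both coordinates carry error and the
   bundle can lie at any angle.
2. **Density map** — `compute_density_map()` builds a kernel density map
   with an isotropic Gaussian kernel (σ between 40 and 80 nm, 60 nm
   default) on a 10 nm grid. The kernel parameter is the Gaussian σ; it
   suppresses shot noise from finite sampling without erasing the bundle's
   cross-section.
3. **Centerline** — `fit_centerline()` follows the density ridge
   column-wise (after rotating the bundle horizontal), drops columns whose
   peak density is below 10% of the global maximum, trims three kernel
   sigmas at each end (one-sided kernel support biases the ridge near the
   edges), and fits a degree-3 polynomial to the ridge by weighted least
   squares.
4. **Distances** — `perpendicular_distances()` computes the signed
   perpendicular distance from every localization to the fitted curve by a
   coarse-to-fine nearest-point search followed by projection onto the
   local tangent.
5. **Profile fit and deconvolution** — `fit_width_profile()` histograms
   the distances in 5 nm bins and fits a single Gaussian (optionally with a
   flat baseline for background events) with Levenberg–Marquardt
   (`minpack.lm::nlsLM`). `correct_for_precision()` removes the
   localization-precision blur in quadrature: σ_corr = √(σ_meas² − σ_prec²)
   with σ_prec the root-mean-square of the contributing events' precisions
   and the fluorophore linker length set to 0 nm. Widths are reported as
   FWHM = 2√(2 ln 2)·σ. When σ_prec ≥ σ_meas the structure is narrower than
   the precision can resolve and the correction refuses with an error
   rather than returning an imaginary width.

```{r width}
sc <- simulate_bundle_localizations(bundle_spec(sigma_true_nm = 30, seed = 7))
w <- measure_bundle_width(sc$table)
c(fwhm_measured = w$fwhm_meas_nm, fwhm_corrected = w$fwhm_corr_nm,
  fwhm_true = sc$truth$fwhm_true_nm)
```

## Blind drift correction

Long acquisitions drift. `estimate_drift()` recovers the trajectory without
fiducials: events are split into temporal bins holding equal event counts
(so late, bleached portions of the stack get as much signal per bin as
early ones), each bin is rendered, and each bin's image is cross-correlated
against the first bin via FFT. The correlation peak is refined to sub-pixel
accuracy with a parabolic fit, and the per-bin offsets are interpolated
piecewise-linearly over frames. Correlating every bin against a fixed
reference rather than chaining neighbors avoids random-walk accumulation of
bin-to-bin errors.

A blind method cannot observe a constant offset (shifting all frames
equally moves the reconstruction, not the correlations), so accuracy is
assessed on the mean-removed residual trace. With ~10⁵ events over 20,000
frames, injected linear drift is recovered to a few nm RMS.

```{r drift}
drift <- linear_drift(1000, 30, 10)
tabd <- simulate_bundle_localizations(
  bundle_spec(density_per_um = 3000, n_frames = 1000, seed = 3))$table
trace <- estimate_drift(inject_drift(tabd, drift), n_bins = 5)
head(drift_at(trace, c(1, 500, 1000)))
```

## Skeletonization and branch metrics

`analyze_network()` chains binarization, optional smoothing, hole filling,
thinning, branch decomposition, and pruning.

- **Binarize** — `otsu_threshold()` maximizes the between-class variance
  over the image histogram (exact integer search for 8-bit-like data, a
  256-bin search otherwise; smallest threshold on ties); foreground is
  strictly above threshold. A manual threshold is also supported.
- **Smooth** — `smooth_and_rebinarize()` applies a 2D Gaussian (σ 3–4 px)
  and re-binarizes with a fresh Otsu threshold, homogenizing pixelation of
  sparse labeling. For already-clean binary ribbons it is better skipped:
  smoothing a clean mask only distorts its geometry.
- **Thin** — `skeletonize()` reduces the mask to a one-pixel-wide
  8-connected skeleton by Guo–Hall two-subiteration thinning, which
  preserves topology (re-skeletonizing a skeleton is the identity).
- **Classify and decompose** — skeleton pixels are endpoints (one
  neighbor) or junctions. Junctions are detected by crossing number — the
  number of background→foreground transitions around the pixel's 8-ring —
  being at least 3, which, unlike a raw neighbor count, does not misfire on
  pixels merely adjacent to a crossing. Branch segments are traced between
  nodes; at forks next to a junction mouth the trace follows the direction
  most aligned with its current travel, so two branch mouths that touch
  diagonally across a junction are not spliced together.
- **Measure** — branch lengths use the 8-connected geodesic metric (axial
  step = one pixel, diagonal step = √2 pixels). Three systematic thinning
  artifacts are corrected at measurement time: (i) junction clusters are
  displaced into the wedge between arms, so the node position is
  re-estimated as the least-squares intersection of the incident branch
  directions; (ii) free tips retract inside the ribbon, so endpoint
  branches are extended along their local direction until they exit the
  foreground mask; (iii) staircase parity wobble inflates path length, so
  each segment is reported as the shortest geodesic through a one-pixel
  corridor of the mask around the traced path.
- **Prune** — `prune_branches()` removes endpoint-terminated spurs shorter
  than 120 nm, re-thins, and recomputes the node classification until
  stable. `network_metrics()` then reports branch count, lengths, and the
  normalized branch number (branch pixels over all skeleton pixels).

```{r skeleton}
net <- simulate_network_image(random_network_spec(n_edges = 12, seed = 5))
met <- analyze_network(net$image, min_branch_nm = 120, smooth = FALSE)$metrics
c(branches = met$branch_count, truth = net$truth$branch_count)
```

## AFM elasticity

For a sharp indenter the Hertz contact force is
F = C·E/(1−ν²)·(δ−δ₀)², with C = (2/π)·tan α for a cone and
C = 0.7453·tan α for a four-sided pyramid. `detect_contact_point()` finds
the contact δ₀ by a grid search (flat baseline before contact, Hertz
parabola after, minimizing total squared residual) followed by a continuous
polish of (baseline, δ₀, E) with Levenberg–Marquardt, since the true
contact generally falls between samples. Fits are restricted to gentle
loading (≤ 0.5 nN), and the window is applied through the model — the
indentation depth at which the fitted force reaches the cap — rather than
through the noisy measured force, which would preferentially discard
high-noise samples near the cap and bias the modulus low.
`map_elasticity()` fits a grid of curves into a spatial modulus map and a
probability histogram; failed fits become missing cells.

```{r hertz}
sim <- simulate_force_curve(2000, "cone", noise_frac = 0.05, seed = 1)
fit_hertz(sim$curve)$E_pa
```

## Myotube indices

From labeled nuclei and desmin masks, `assign_nuclei()` assigns each
nucleus to the desmin object containing its centroid (a majority-overlap
rule is available; the centroid rule is the default because it gives every
nucleus exactly one unambiguous vote). `compute_indices()` then reports the
differentiation index (desmin-positive objects per nucleus), the fusion
index (fraction of nuclei residing in myotubes, i.e. desmin objects with at
least two nuclei), the myotube nuclearity histogram in categories
{2, 3–5, >5}, and per-myotube morphometrics (area, length along the
skeleton's longest geodesic, major axis).

```{r myotube}
fx <- generate_myotube_masks(100, myotube_assignment = 30,
                             n_desmin_pos_cells = 40, seed = 61)
met <- compute_indices(fx$nuclei, fx$desmin, fx$pixel_size_um)
c(differentiation = met$differentiation_index, fusion = met$fusion_index)
```

## Limitations

- Blind drift correction cannot recover a constant offset, and its
  accuracy degrades below roughly 10⁴ events per temporal bin.
- Precision deconvolution assumes the measured profile is Gaussian; a
  structured (e.g. hollow) cross-section would need a different forward
  model.
- Branch lengths carry the intrinsic digitization excess of the
  axial/diagonal geodesic metric (up to ~8% for straight lines at 22.5°);
  the corridor geodesic removes parity wobble but not this metric floor.
- The Hertz model assumes a sharp rigid indenter on a flat, semi-infinite,
  linear-elastic sample; moduli from thin or curved samples are effective
  values.
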