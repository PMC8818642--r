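# nanometrics

Quantitative nanoscale imaging analysis of the muscle cell cytoskeleton.

Syndecan-4 silencing remodels the cortical cytoskeleton of differentiating
myoblasts. Detecting that remodeling quantitatively requires measurements at
scales conventional light microscopy cannot resolve: the width of individual
cortical actin bundles (tens of nm), the branching topology of the actin
network, the cell's elastic modulus under gentle indentation, and — at the
tissue-culture scale — how well the cells fuse into myotubes. `nanometrics`
implements that measurement chain end to end:

- **Localization tables** (`loc_table`, `filter_by_precision`,
  `render_image`): read, filter (precision < 40 nm), and render dSTORM
  single-molecule localization events into 20 nm/px superresolution images.
- **Blind drift correction** (`estimate_drift`, `correct_drift`):
  fiducial-free recovery of the stage drift trajectory by FFT
  cross-correlation of temporally binned reconstructions against a fixed
  reference bin, with sub-pixel parabolic peak refinement.
- **Bundle width** (`measure_bundle_width`): total-least-squares
  orientation, Gaussian kernel density map (σ = 40–80 nm), polynomial
  centerline along the density ridge, signed perpendicular distance
  histogram, single-Gaussian fit, and localization-precision deconvolution
  in quadrature (linker length 0 nm). Widths are reported as
  FWHM = 2√(2 ln 2)·σ.
- **Skeleton morphometry** (`analyze_network`): Otsu or manual
  binarization, optional Gaussian smoothing + re-binarization, Guo–Hall
  thinning, branch decomposition with crossing-number junction detection,
  120-nm spur pruning, geodesic branch lengths (axial pixel / diagonal
  √2·pixel), and the normalized branch number.
- **AFM elasticity** (`fit_hertz`, `map_elasticity`): Hertz-model Young's
  moduli from force-indentation curves (cone and four-sided pyramid tips),
  automatic contact-point detection with continuous refinement, loading
  force capped at 0.5 nN, spatial modulus maps and probability histograms.
- **Myotube indices** (`compute_indices`): differentiation index,
  fusion index, nuclei-per-myotube categories {2, 3–5, >5}, and per-myotube
  morphometrics from labeled nuclei/desmin masks.

Every pipeline has a paired synthetic-scene generator
(`simulate_bundle_localizations`, `simulate_network_image`,
`simulate_force_curve`, `generate_myotube_masks`, …) that records exact
ground truth, so parameter recovery is testable without instrument data.

## Worked example

Measure the width of a synthetic cortical actin bundle with a true
cross-section σ = 30 nm (FWHM 70.6 nm) and realistic per-event
localization precision:

```r
library(nanometrics)

sc <- simulate_bundle_localizations(bundle_spec(sigma_true_nm = 30, seed = 7))
measure_bundle_width(sc$table)
#> width_measurement: FWHM_meas 80.3 nm, FWHM_corr 71.6 nm
#>   sigma_meas 34.10 nm, sigma_prec 15.47 nm, sigma_corr 30.39 nm
#>   5143 events, Gaussian fit R^2 0.996, centerline degree 3
```

The measured 80.3 nm FWHM is blurred by the ~15 nm localization precision;
quadrature deconvolution recovers 71.6 nm against the 70.6 nm truth.

Skeletonize a rasterized random filament network and recover its branches:

```r
net <- simulate_network_image(random_network_spec(n_edges = 12, seed = 5))
analyze_network(net$image, min_branch_nm = 120, smooth = FALSE)$metrics
#> 12 branches (truth: 12), mean branch length 295.7 nm (truth 285.8 nm),
#> normalized branch number 0.959
```

Fit a Young's modulus from a noisy force curve (true E = 2000 Pa):

```r
sim <- simulate_force_curve(2000, "cone", noise_frac = 0.05, seed = 1)
fit_hertz(sim$curve)
#> hertz_fit (cone): E = 2005 Pa, contact 0.1 nm, baseline -1.1e-05 nN,
#>   RMS 0.011 nN (323 pts)
```

Compute fusion metrics from labeled masks (100 nuclei, one 30-nucleus
myotube, 40 mononucleated desmin-positive cells):

```r
fx <- generate_myotube_masks(100, myotube_assignment = 30,
                             n_desmin_pos_cells = 40, seed = 61)
met <- compute_indices(fx$nuclei, fx$desmin, fx$pixel_size_um)
met$differentiation_index  #> 0.41
met$fusion_index           #> 0.3
```

## Analysis workflow

Numbered drivers under `analysis/` reproduce the study-style analyses on
synthetic scenes and write tables to `results/`:

```sh
Rscript analysis/01_bundle_width.R      # two populations, true FWHM ratio 1.5
Rscript analysis/02_drift_correction.R  # closed-loop drift recovery
Rscript analysis/03_network_skeleton.R  # branch counts/lengths vs truth
Rscript analysis/04_afm_elasticity.R    # bimodal stiffness map + histogram
Rscript analysis/05_myotube_indices.R   # DI / FI / nuclearity histogram
```

Representative output (deterministic seeds):

- `01`: mean corrected FWHM 70.6 nm (control) vs 106.3 nm (silenced
  analogue) — estimated ratio 1.505 against a true 1.500.
- `02`: 105,105 events over 20,000 frames, injected 0→100 nm linear drift,
  RMS residual trace error 2.73 nm.
- `03`: exact branch count in 50/50 networks; max branch-length deviation
  42.8 nm (tolerance (1+√2)·pixel = 48.3 nm).
- `04`: 144/144 curves fitted; median modulus error 2.1% at 5% force noise
  (median fits 1003 / 4012 Pa against 1000 / 4000 Pa).
- `05`: differentiation/fusion indices and nuclearity histograms for a
  differentiating vs a poorly fusing field.

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .

# full test suite against the installed package (~3 min, 1 CPU)
Rscript -e 'testthat::test_dir("tests/testthat", package = "nanometrics",
                               load_package = "installed")'

# acceptance report (~2 min): headline recovered quantities as JSON
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The test suite (398 assertions) covers each module against independent
oracles — closed-form values, brute-force recomputation, and generator
ground truth — plus end-to-end recovery blocks: bundle-width recovery over
a σ_true × σ_prec grid, a true 1.5× width-ratio experiment, drift
correction at full stack size, Otsu vs exhaustive search on 200 images,
branch topology recovery over 100 random networks, Hertz recovery with and
without noise, and exact index arithmetic on mask fixtures.

A methods vignette describing each algorithm and its design rationale is in
`vignettes/superresolution-morphometrics.Rmd`.
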