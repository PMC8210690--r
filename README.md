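# sngfr — single-nephron GFR from intravital dye-front imaging

`sngfr` measures **single-nephron glomerular filtration rate (snGFR)** from
intravital multiphoton microscopy of the mouse kidney. After intravenous
injection of a freely filtered, non-resorbable fluorescent dye (Lucifer
Yellow), the dye front advances through the proximal tubule (PT) at the
filtration flow rate; tracking that front against the tubule's true 3D
volume turns an image series into a flow measurement in nl/min.

The package implements two workflows:

- **Extended workflow** (continuous + 3D volume). Along a hand-drawn
  polyline ROI tracing the PT, the dye intensity is sampled in every frame
  of the time series (a kymograph *I(s, t)*). A co-registered 3-channel
  z-stack is denoised with a 3D median filter, cleared of spectral
  bleed-through by channel subtraction, and segmented by a
  distance-transform-seeded 3D watershed; the basins the ROI traces form
  the PT mask. Projecting mask voxels onto the ROI converts arclength *s*
  to cumulative tubule volume *V(s)*. A global front threshold is set at
  the temporal turning point (maximum slope) of the arrival curves; the
  front volume `V_t = V(s*)` located in each frame is regressed on frame
  index,

  `V_t = β0 + β1 t`,    `snGFR = β1 · fps · 60 · 10⁻⁶  [nl/min]`,

  with R² reporting how well a constant-flow front explains the data.

- **Two-point (legacy) workflow**, the previously published comparator:
  transit time of the front between the ROI's endpoints and a cylinder
  volume `π (d̄/2)² L` from the mean of five manually measured diameters;
  `snGFR = V / Δt`.

A **phantom generator** renders a tubule filling at a known volumetric flow
(time series + 3-channel z-stack + ROI + ground truth), so the entire
pipeline is testable without any microscope data, and **repeatability
statistics** (per-dataset CV, workflow mean ± SD, two-sample
Kolmogorov–Smirnov test) quantify how much the reduced user interaction of
the extended workflow improves reproducibility.

## Worked example

```r
library(sngfr)

# a synthetic acquisition: straight tubule, lumen radius 15 um, filled at
# a ground-truth 1.7 nl/min, 5% Gaussian noise, 30 frames at 6 fps
ph  <- render_phantom(phantom_spec(noise_sigma = 0.05, seed = 3))

cfg <- run_config(ph$series, ph$volumes, ph$roi, ph$series$meta,
                  out_dir = "out", dataset_id = "demo")
fit <- run_extended(cfg)
summary(fit)
#> Single-nephron GFR, extended (continuous + 3D volume) workflow
#>
#>   snGFR:            1.727 nl/min
#>   slope:            4797 um^3/frame at 6 fps
#>   R-squared:        1
#>   front threshold:  98.46 (intensity units)
#>   frames used:      23
#>   PT length:        171 um
#>   PT volume:        125145 um^3

run_legacy(cfg, diameters_um = c(28, 30, 31, 29, 30))
#> Single-nephron GFR (two-point transit method)
#>   snGFR: 1.765 nl/min  (V = 117671 um^3 over 4 s)
```

The estimate (1.727 nl/min) recovers the phantom's true 1.7 nl/min within
2%; the threshold sits near half of the 200-unit dye plateau, as expected
for a sigmoidal arrival curve; PT volume is the watershed-segmented lumen,
within voxelization error of the analytic `π r² L = 120 873 um³`. `out/`
receives the kymograph and volume-profile CSVs, the label/mask TIFFs for
visual verification, the result CSV and a JSON run log.

Repeatability analysis of replicate measurements:

```r
tab <- published_repeatability()      # bundled per-dataset summary table
aggregate_cv(tab[tab$workflow == "extended", "relative_sd_percent"])
#> [1] 10.35473
aggregate_cv(tab[tab$workflow == "previous", "relative_sd_percent"])
#> [1] 38.74653
```

A command-line front end (subcommands `extended`, `legacy`, `phantom`,
`stats`) is installed at `system.file("cli", "sngfr.R", package = "sngfr")`.

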