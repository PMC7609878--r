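# laurdanGP

Membrane lateral packing order from Laurdan general polarization (GP),
for cell biologists and biophysicists tracking differentiation-linked
membrane condensation — e.g. keratinocytes driven through the calcium
switch — in living cells.

Laurdan's emission red-shifts as water penetrates loosely packed
bilayers. The GP index condenses the two-band readout into one bounded
statistic,

    GP = (I440 − I490) / (I440 + I490),   GP ∈ [−1, 1],

with `I440`/`I490` the mean emission intensities over 440 ± 10 nm and
490 ± 10 nm. Higher GP = tighter lipid packing = more advanced
differentiation. The package implements both measurement routes:

* **Imaging** — confocal lambda stacks (32 channels, 415–691 nm at
  8.9 nm) are fitted pixel-by-pixel with a gamma-variate curve,
  `A·((λ−λ0)/β)^α·exp(−(λ−λ0)/β)`, and reduced to a masked GP map with
  blue→red pseudo-colour rendering. Whole-image GP histograms are
  decomposed by a double-Gaussian fit into a low-GP cytosolic and a
  high-GP plasma-membrane population.
* **Plate reader** — whole-well spectra (405–600 nm, ≥ 25 flashes
  averaged) give one ensemble GP per well; conditions are compared with
  one-way ANOVA + Tukey HSD and box-plot summaries.

A synthetic generator (two-state spectral mixing, annular
membrane/interior cell phantoms, Hill-type calcium→order mapping with
collapse at 5 mM, Poisson photon noise) provides ground truth for every
stage; no experimental data are required to test the pipeline.

## Worked example

```r
library(laurdanGP)

basis   <- make_basis_spectra()                      # 440/490 nm two-state model
phantom <- make_cell_image(cell_phantom_config(seed = 1), basis)
map     <- compute_gp_map(phantom$image, mode = "fit_eval")
map
#> <gp_map: 48 x 48 px, 1020 valid (44.3%), mode fit_eval, GP range [-0.175, 0.225]>

fit_gaussian_mixture(gp_values(map), k = 2, seed = 1)
#> <mixture_fit: k = 2, method = histogram_ls, converged = TRUE, score = -4528>
#>  component                     label       mean         sd    weight
#>          1        cytosolic (low-GP) -0.1298286 0.01534702 0.7018949
#>          2 plasma membrane (high-GP)  0.1835309 0.01431982 0.2981051
```

The two mixture means recover the phantom's ground truth: the interior
(ordered fraction 0.3, analytic GP ≈ −0.14) and the membrane ring
(ordered fraction 0.8, analytic GP ≈ 0.18), assigned purely by mean
ordering, never by pixel position.

The plate route across a calcium series:

```r
plate <- make_calcium_series(
  calcium_series_config(calcium_levels = c(0.06, 0.3, 0.75, 1.5, 2.5),
                        seed = 1))
wells <- plate_gp_table(plate$records)
compare_conditions(wells$gp, wells$condition_mM)
#> <condition_comparison: F(4, 10) = 1810.809, p = 2.99e-14>
#>  condition n       mean           sd ...
#>       0.06 3 0.01723236 0.0012511540
#>        0.3 3 0.02996611 0.0002286122
#>       0.75 3 0.04710037 0.0007350384
#>        1.5 3 0.05700445 0.0004403947
#>        2.5 3 0.06177216 0.0007376691
```

Well GP rises monotonically with calcium (each well pools the ordered
membrane with the fluid interior, so ensemble values are intermediate
between the two population GPs). End-to-end drivers with provenance
logging: `run_imaging_pipeline()`, `run_plate_pipeline()`,
`make_demo_dataset()`, and a CLI at `inst/cli/gp`
(`gp simulate | map | well | populations | compare | demo | run`).

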