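---
title: "Quantifying membrane packing order with Laurdan general polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane packing order with Laurdan general polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laurdanGP)
```

## The measurement

Laurdan is a lipophilic, polarity-sensitive fluorophore that inserts into
lipid bilayers parallel to the acyl chains. In a loosely packed (fluid)
membrane, water penetrates the bilayer, the excited dye relaxes against the
polar environment, and emission shifts red (toward ~490 nm). In a tightly
packed (ordered) membrane the shift is suppressed and emission stays blue
(~440 nm). The *general polarization* index condenses the two-band
ratiometric readout into one number,

$$ GP = \frac{I_{440} - I_{490}}{I_{440} + I_{490}}, \qquad GP \in [-1, 1], $$

where $I_{440}$ and $I_{490}$ are emission intensities in the
$440 \pm 10$ nm and $490 \pm 10$ nm bands. Higher GP means tighter lipid
lateral packing. During keratinocyte differentiation (driven in vitro by
raising extracellular calcium from 0.06 mM toward 1.5 mM and beyond),
membranes become more ordered and GP rises; this package treats GP as a
live-cell differentiation readout with two measurement routes:

* **Imaging route** — confocal lambda stacks (32 channels, 415–691 nm at
  8.9 nm) are reduced pixel-by-pixel to a GP map; the pixel histogram is
  decomposed into a low-GP (cytosolic membranes) and a high-GP (plasma
  membrane) population by a double-Gaussian fit.
* **Plate-reader route** — whole-well emission spectra (405–600 nm,
  averaged over ≥ 25 flashes) give one ensemble GP per well, an average
  over both populations; conditions are compared by one-way ANOVA with
  Tukey's HSD.

## Band statistic

Band intensity is the **mean** (not the sum) of the samples inside the
closed band. This makes GP invariant to how many channels fall inside a
band, so 1 nm plate-reader grids and 8.9 nm confocal grids produce
comparable numbers. `band_intensity()` is deliberately trivial; the test
suite checks it against an independent brute-force summation oracle to
machine precision.

Pixels whose bands sum to zero are *masked invalid*, never set to 0: a GP
of 0 is a meaningful physical value (equal band intensities), whereas an
empty pixel is simply not a measurement.

## The per-pixel spectral model

The imaging route fits each pixel's emission spectrum with a gamma-variate
curve

$$ f(\lambda) = A \left(\frac{\lambda - \lambda_0}{\beta}\right)^{\alpha}
   e^{-(\lambda - \lambda_0)/\beta}, \quad \lambda > \lambda_0, $$

a skewed unimodal shape with analytic peak at $\lambda_0 + \alpha\beta$.
Numerical choices:

* The amplitude $A$ is profiled out analytically (linear least squares
  given the shape), leaving a 3-parameter problem solved by Nelder–Mead
  polished with BFGS on an unconstrained scale
  $(\log(\lambda_\mathrm{floor} - \lambda_0), \log\alpha, \log\beta)$.
* The onset $\lambda_0$ is constrained below the first wavelength that
  carries signal. Real Laurdan emission is already rising at the blue edge
  of the detection window; without the constraint, noisy red-shifted
  pixels occasionally fit an onset above 440 nm, which zeroes $I_{440}$
  and fabricates a spurious GP = −1 population.
* Starts come from spectral moments via the gamma relations
  $\mathrm{mean} - \lambda_0 = (\alpha + 1)\beta$ and
  $\mathrm{var} = (\alpha + 1)\beta^2$; a few perturbed restarts run only
  if the first fit leaves > 5 % of the spectral energy unexplained.
* Non-convergence or a non-positive solution flags the pixel
  (`converged = FALSE`); in batch use the pixel is masked, never an error.

On noiseless sampled gamma variates the fit recovers
$(\lambda_0, \alpha, \beta, A)$ to relative error below $10^{-6}$
(tested).

**How GP is read off the fit.** The default mode `fit_eval` averages the
*fitted* curve over the same $\pm 10$ nm bands, so the fit acts purely as
a denoiser and the statistic stays consistent with the band (plate) path:
on noiseless two-state phantoms the two paths agree within 0.009 GP,
comfortably inside the 0.02 consistency budget we test. Evaluating the
fitted curve at exactly 440/490 nm (mode `fit_point`) is also available
but systematically disagrees with the band path by up to 0.026 GP,
because a point on a curved spectrum is not its band mean. The
plugin-faithful `nearest_channels` mode takes the single observed
channels nearest 440/490 nm (441.7 and 486.2 nm on the confocal grid);
being up to ~4 nm off-center it is the coarsest statistic and is kept for
comparison, not as a default.

## Background masking

A pixel enters the GP statistics only if its summed spectrum exceeds
*all* of: an absolute count floor (default 0), the 5th percentile of
nonzero pixel sums (`quantile = 0.05`), and 5 % of the brightest pixel's
sum (`rel_floor = 0.05`). The third criterion is this package's addition:
a dim flat background under photon noise never reaches exactly zero
counts, so purely quantile-based masking admits background as a spurious
GP ≈ 0 population that corrupts the two-component decomposition. All
three knobs are configurable per call (`"quantile:q"`,
`"intensity_threshold:t"`, or an explicit list).

## Population decomposition

GP histograms use a 0.02 GP bin width over $[-1, 1]$ by default; values
outside the range are clipped into the edge bins and counted. The primary
mixture fit mirrors the published procedure: nonlinear least squares of a
k-Gaussian curve to the *normalized frequency histogram*
(`histogram_ls`), multi-start under a fixed seed. An independent EM fit
on the raw pixel values (`em`) serves as a cross-check; the two agree on
simulated data and on phantoms. Components are reported sorted by
ascending mean, and with $k = 2$ the labels are purely rank-based:
low-GP = cytosolic, high-GP = plasma membrane. No spatial information
enters the labelling, exactly as in whole-image analysis.

$k = 2$ is the default (fixed a priori in the published analysis);
`select_component_count()` is an audit step that fits $k \in \{1,2,3\}$
and minimizes BIC, with ties toward fewer components. BIC is always
evaluated on the raw values so scores are comparable across $k$ and
across fit methods.

Ensemble (well) GP defaults to *GP of the flash-mean spectrum*; the
alternative mean-of-per-flash-GPs is available (`both = TRUE`) and agrees
closely at realistic counts. Wells with fewer than 25 flashes trigger a
warning, not an error.

## The synthetic world

Because the assay's numbers come from live primary keratinocytes, the
package validates itself on a generator whose ground truth is known by
construction:

* **Two-state linear mixing.** Pixel spectra are convex combinations
  $\phi \cdot S_\mathrm{ordered} + (1 - \phi) \cdot S_\mathrm{disordered}$
  of two unit-peak Gaussian bases (peaks 440/490 nm, width 45 nm). The
  ground truth is the ordered fraction $\phi$, *not* a GP value, so the
  recovered GP is a genuine pipeline output rather than an input echo.
  With the default bases, GP rises monotonically from −0.33 ($\phi = 0$)
  to +0.30 ($\phi = 1$).
* **Cell phantom.** An annular plasma-membrane ring (default
  $\phi = 0.8$, GP ≈ 0.18) around a fluid interior ($\phi = 0.3$,
  GP ≈ −0.14) over a flat 2-count background; brightness 500 expected
  peak counts; channel-wise Poisson noise; everything a pure function of
  (config, seed).
* **Calcium series.** Membrane order follows a Hill-type saturating map
  of calcium. The assay reports only that GP increases monotonically over
  0.06–5 mM, so the map's shape is configuration; the defaults
  (floor 0.80, ceiling 0.97, half-max 0.5 mM, Hill 1.5) place the
  synthetic populations near the printed population GPs (membrane GP
  ≈ 0.18 at 0.06 mM rising to ≈ 0.27, cytosol ≈ −0.17, separated at
  every level). At 5 mM — the collapse concentration — brightness drops
  to 20 % and the membrane ring fragments, emulating the loss of cell
  integrity; the exact collapse numbers are unquantified in the source
  and are simply fixed here.
* **Plate wells** mix the two populations 50/50 on a 1 nm 405–600 nm
  grid, 3 wells × 25 flashes per level by default (the replicate
  structure of the original screen).

What the generator does **not** emulate: optics (no point-spread
function, no detector crosstalk or spectral bleed-through), photobleaching,
3-D structure, cell-to-cell variability within a condition, or autofluorescence.
A green test therefore establishes that the *analysis* recovers a known
two-population membrane-order structure under photon noise — not that the
assay is robust to every instrumental artifact.

## Tolerances worth knowing

| check | tolerance | why |
|---|---|---|
| band oracle vs `band_intensity` | 1e−12 | identical arithmetic, different code path |
| gamma parameter recovery (noiseless) | 1e−6 relative | optimizer precision |
| fit path vs band path | 0.02 GP | model-mismatch budget on two-state spectra |
| whole-image mixture vs region means | 0.05 GP | histogram binning + overlap |
| ensemble (well) vs imaging mean | 0.05 GP | differently weighted averages on different grids |
| Poisson well GP vs noiseless | 0.01 GP | 25-flash averaging at 500 counts |

## Known limitations

* The TIFF layer is a minimal baseline codec (uncompressed grayscale
  strips); compressed, tiled or multi-sample TIFFs and vendor formats
  (.lsm/.czi) are out of scope. OME-XML metadata is not parsed —
  wavelengths travel in a JSON sidecar or an explicit vector.
* The gamma variate is a single-mode model; on strongly bimodal pixel
  spectra (a physical mixture of both states) it is a smoothing
  approximation, which is why the band-consistency budget is 0.02 GP
  rather than machine precision.
* Excitation wavelength is carried as metadata only and never enters a
  computation (the source protocols quote 374, 380 and 405 nm in
  different places).
* No automatic membrane segmentation: region statistics take masks as
  inputs (ROIs were drawn manually in the original workflow).
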