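Package: laurdanGP
Title: Laurdan General-Polarization Analysis of Membrane Packing Order
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies membrane lateral packing order from Laurdan
    fluorescence by the general polarization (GP) index. Supports the
    single-cell imaging route (per-pixel gamma-variate fitting of confocal
    lambda stacks into masked GP maps with pseudo-colour rendering) and the
    ensemble plate-reader route (band-intensity GP from well emission
    spectra averaged over flashes). GP pixel distributions are decomposed
    into cytosolic and plasma-membrane populations by double-Gaussian
    fitting, and conditions are compared by one-way ANOVA with Tukey HSD.
    Includes a synthetic hyperspectral-cell and calcium-series generator
    with known ground-truth order, lambda-stack and plate-reader CSV I/O,
    and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
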