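Package: soilcos
Title: Synchronous 2D Correlation Spectroscopy and Band-Selection PLSR for
    Soil Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing visible/near-infrared (vis-NIR, 400-2450 nm)
    absorbance spectra of moist soils with synchronous two-dimensional
    correlation spectroscopy (2D-COS). Treating soil moisture and soil organic
    matter (SOM) as perturbation variables, the package builds dynamic spectra
    and synchronous correlation maps, detects auto-peaks along the map
    diagonal, and uses the detected moisture bands to construct spectral band
    sets for SIMPLS partial least squares regression (PLSR) of SOM content,
    assessed by R2, RMSE and RPD under nested five-fold cross-validation. A
    synthetic spectra generator reproduces the statistical structure of
    moist-soil spectra (water peaks with moisture-driven red-shift, weak SOM
    features quenched by moisture, baseline darkening, wavelength-dependent
    noise) so that every stage of the pipeline can be exercised and tested
    without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
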