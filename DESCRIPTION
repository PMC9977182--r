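Package: prairieCH4
Title: Chamber-to-Landscape Upscaling of Prairie Wetland Methane Emissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling methane (CH4) emissions from depressional
    prairie wetlands across scales. Computes static-chamber CH4 fluxes from
    headspace concentration changes via the ideal gas law, derives water-filled
    pore space and Q10 temperature sensitivities, fits a penalized additive
    (GAM) model of positive log-normal fluxes with wetland and chamber random
    effects, upscales flux predictions to a 30-m wetland landscape with a
    bootstrap tree ensemble, integrates biweekly flux rates to cumulative
    annual emissions under a winter boundary-rate assumption, and projects
    emissions under warming-by-wetland-extent scenario ensembles. Includes a
    synthetic-data module that generates chamber datasets and wetlandscape
    raster time series with known generating truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    ranger,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
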