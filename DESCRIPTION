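Package: gfelute
Title: Growth Factor Release and Degradation Kinetics for Eluting Coatings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the fate of a growth factor released from an eluting
    surface coating (such as a polyelectrolyte multilayer) into a culture
    well. Fits apparent first-order degradation half-lives from
    immunoassay timecourses over an equilibration-aware window,
    degradation-corrects cumulative release measured by
    sampling-with-replacement studies, fits the Korsmeyer-Peppas power
    law to fractional release, and forward-simulates real-time
    growth-factor concentration under eluting-coating or exogenous bolus
    dosing. Includes Sauerbrey analysis of quartz crystal microbalance
    traces for layer-by-layer assembly and synthetic-data generators for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
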