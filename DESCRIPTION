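Package: azquant
Title: Optical Quantal Analysis of Synaptic Release at Single Active Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for optical quantal analysis of
    neurotransmitter release at individual presynaptic active zones (AZs),
    as performed at the Drosophila larval neuromuscular junction with
    postsynaptically targeted calcium indicators. Raw time-lapse
    fluorescence stacks are Gaussian filtered, movement corrected, and
    baseline subtracted; single-vesicle fusion flashes are detected,
    assigned to AZs by centroid proximity, and converted into per-AZ
    evoked release probabilities and spontaneous rates with mean+2SD
    classification of high-releasing sites. Companion modules quantify
    structural-channel fluorescence and its correlation with release,
    measure postsynaptic receptor-field morphology (radial profiles,
    GluRIIB-style ring segregation, FWHM diameters), and track AZ
    identities across multi-day imaging sessions for synapse birth-dating
    and maturation timing. A calibrated synthetic-data generator produces
    movies, channel images, and developmental series with known ground
    truth for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
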