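Package: conshab
Title: Multiscale Consensus Presence-Only Habitat Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building consensus presence-only habitat suitability
    models at multiple spatial scales, after the workflow used for large
    carnivore conservation planning: telemetry screening and temporal
    subsampling, raster habitat covariates (distance, focal density, terrain
    ruggedness, patch shape and contiguity), a from-scratch L1-regularized
    maximum-entropy (Gibbs) model with hinge features and kernel-density
    bounded background sampling, Mahalanobis-distance suitability with
    chi-square probability output, cross-validated accuracy assessment (AUC,
    continuous Boyce index, TSS) with maximum sensitivity-plus-specificity
    thresholding, consensus averaging and thresholded mosaicking of local
    management-unit models into a statewide map, and threat and protection
    overlay accounting. Includes a synthetic-landscape and virtual-species
    generator so the full pipeline is testable end to end without external
    geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
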