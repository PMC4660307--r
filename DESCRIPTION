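Package: ffsoc
Title: Fission-Fusion Social Structure Analysis from Photo-Identification
    Sighting Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the social structure of fission-fusion animal
    societies from photo-identification sighting records, modelled on the
    workflow used for coastal dolphin communities. Computes half-weight
    association indices (HWI) and their gregariousness-corrected variant
    (HWIG), tests for nonrandom association with group-within-sample
    permutations of the sighting data, compares association strength within
    and between community classes with node-label permutation and
    randomization tests, builds average-linkage social dendrograms with
    cophenetic validation and Newick export, and fits exponential-family
    models to standardized lagged association rates with QAIC selection and
    jackknife precision. A configurable synthetic fission-fusion society
    generator provides seeded, ground-truthed sighting datasets so the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
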