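Package: oligostate
Title: Oligomeric-State Inference for Small Dimerization Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for deciding whether a small protein
    domain is a monomer or a dimer in solution, built around the evidence
    streams used to characterize alpha-helical hairpin dimerization domains
    of STAR-family RNA-binding proteins: analytical size-exclusion
    chromatography (column calibration, apparent molecular weights, Stokes
    radii, aggregation numbers and mixture dimer fractions), multi-model
    structure ensembles (helix detection, inter-helix and docking angles,
    ensemble RMSD, solvent-accessible and buried interface areas, typed
    interface contacts), backbone 15N relaxation (rotational correlation
    time, structured-region delineation, exchange broadening, shift
    dispersion), and two equilibrium models (two-state dimer thermal
    unfolding and single-species sedimentation equilibrium). A set of
    synthetic-data generators with known ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
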