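Package: dropoffr
Title: Drop-Off LNA Probe Assays for Quantifying CRISPR Genome Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design and analysis toolkit for internally referenced drop-off
    qPCR/dPCR assays that quantify CRISPR-Cas9 on-target editing in mosaic
    founder animals. Implements nearest-neighbor DNA hybridization
    thermodynamics with locked-nucleic-acid (LNA) perturbations and
    divalent-cation salt correction; constraint-based design of drop-off
    assays (primer pair, LNA target probe at the cut site, internal reference
    probe) and competitive allele-specific probe pairs; unedited-allele
    quantification from multiplex qPCR Cq tables by the delta-delta-Cq method
    with calibration-slope checking; digital PCR partition classification and
    Poisson occupancy estimation with confidence intervals; pairwise alignment
    and taxonomy-based classification of amplicon clone sequences including
    homology-directed-repair component decomposition; endpoint-fluorescence
    allelic-discrimination genotyping; and seeded generative models of mosaic
    allele populations and assay signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
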