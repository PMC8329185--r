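Package: halotrace
Title: Bead Halo Assay Quantitation and Evolutionary Trace Analysis of
    Nucleocytoplasmic Transport Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nucleocytoplasmic transport receptor (NTR) to cargo
    binding from two-channel (mCherry/GFP) confocal bead halo assay images:
    bead segmentation with area/circularity/edge filters, ring-shaped regions
    of interest with background rings, background-subtracted GFP/mCherry
    ratios, wild-type normalization, three-level discretization, exact
    Mann-Whitney testing, and Ward clustering of the discretized binding
    profiles. Also provides a modified evolutionary trace analysis that scores
    multiple-alignment columns for differentiation between two paralog
    ortholog groups by symmetric Kullback-Leibler divergence of
    Gerstein-Sonnhammer-Chothia weighted, Dirichlet-smoothed amino-acid
    profiles, a sliding-window scanner for arginine/serine/tyrosine-rich
    (RSY-rich) segments, and seeded synthetic-data generators with ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Biostrings,
    ape,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
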