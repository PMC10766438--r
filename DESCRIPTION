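Package: clonverge
Title: Convergent Clonal Family Discovery in Single-Cell Antibody Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytics for paired-chain single-cell B-cell receptor
    repertoires, aimed at discovering convergent (public) IgE clonal
    families such as those arising in peanut allergy. Provides AIRR
    rearrangement and count-matrix input/output, cell- and sequence-level
    quality control, clonal family construction by shared VH V gene,
    J gene and CDR3 length with identity-threshold clustering,
    cross-subject convergence annotation, pairwise edit-distance
    matrices, somatic hypermutation estimation, aligned CDR3 logo
    position-frequency matrices, plasmablast versus memory cell-state
    classification from expression counts, linear peptide tiling and
    repeat-motif scanning for epitope localization, and a synthetic
    repertoire generator with full ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Biostrings,
    Matrix,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
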