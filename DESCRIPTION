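Package: pepQSAR
Title: Factor-Analysis Amino-Acid Scales and QSAR Modelling for Peptidomimetic Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives low-dimensional amino-acid descriptor scales from large
    residue-by-property matrices by principal-component extraction with
    Kaiser-normalized promax rotation, encodes peptides built from natural and
    non-natural residues as positional factor-score descriptors, and fits and
    validates quantitative structure-activity relationship (QSAR) models:
    NIPALS partial least squares with leave-one-out cross-validation,
    genetic-algorithm variable selection, and stepwise linear discriminant
    analysis with partial-F entry/removal. Includes Y-randomization and
    k-means odd/even split validation, threshold-rule enumeration of candidate
    peptidomimetics, synthetic fixture generators with known ground truth, and
    CSV/JSON input/output with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'cli.R'
    'encoding.R'
    'design.R'
    'pls.R'
    'gapls.R'
    'lda.R'
    'pepQSAR-package.R'
    'scales.R'
    'synthetic.R'
    'validation.R'
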