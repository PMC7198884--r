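Package: corsym
Title: Binary Matrix Scoring of Corolla Symmetry
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies corolla (flower) symmetry from hierarchical binary
    regularity traits. Six binary sub-dimension judgements per flower are
    reduced to a three-dimensional binary vector (corolla-, petal- and
    petal-local regularity), converted to a decimal symmetry index under
    positional weights 2^(j-1), and classified into named symmetry types.
    Includes group-level analytics (type weight distributions, coefficients
    of variation, integrated symmetry indices, between-group weight ratios,
    per-dimension regularity and decay-trend curve fits), validation of the
    parent-progeny symmetry-dominance rule against pedigree tables, a seeded
    synthetic-cohort generator, CSV readers and writers with row-level
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
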