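Package: neoprior
Title: Neoantigen Prioritization from Somatic Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Expression-aware filtering of somatic missense variants,
    design of mutant long peptides and MHC class I epitope windows,
    consensus scoring of predictor percentile ranks with a pluggable
    mock predictor ensemble, ELISPOT-based immunogenicity selection and
    cross-reactivity assessment, and single-cell quantification of
    mutant-allele expression and parent-gene signature scores. Includes
    a seeded synthetic-data generator with planted ground truth so the
    whole pipeline is testable end to end, and a manifest-producing
    orchestrator for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'binding.R'
    'constructors.R'
    'filtering.R'
    'immunogenicity.R'
    'io.R'
    'neoprior-package.R'
    'peptides.R'
    'pipeline.R'
    'sc_expression.R'
    'simulate.R'
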