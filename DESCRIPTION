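Package: koactivator
Title: Packaging, Activation, and Composition of Computable Biomedical
    Knowledge Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infrastructure for managing computable biomedical knowledge
    (CBK) models as Knowledge Objects: compound digital objects bundling a
    persistent identifier, metadata, a deployment description, an OpenAPI
    3.0 service description, and executable payload code. Packages can be
    read, written, and validated; activated into an in-process runtime
    behind an API-gateway router that maintains a live runtime context; and
    composed into serial, hierarchical, and conditional composite models
    via generated executive submodels. Ships a demonstration composite for
    individualized precision prevention that ranks 21 preventive services
    by estimated life-gain in years using life-table survival arithmetic
    with synthetic hazard-ratio parameters, plus generators for synthetic
    life tables, patient records, and the full 42-model demonstration
    shelf.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'zip-archive.R'
    'ko-parse.R'
    'ko-load.R'
    'ko-validate.R'
    'ko-write.R'
    'adapters.R'
    'runtime-context.R'
    'activator.R'
    'http-gateway.R'
    'composition.R'
    'life-table.R'
    'ipp-formulas.R'
    'ipp-catalog.R'
    'ipp-shelf.R'
    'ipp-run.R'
    'synthetic-patients.R'
    'cli.R'
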