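Package: bcrlik
Title: Masked-Language-Model Likelihood Analysis of B Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Relates per-residue likelihoods from masked protein language
    models to signatures of in vivo B cell selection and evolution.
    Computes sequence pseudolikelihoods (SP) of paired heavy/light B cell
    receptor sequences under several input-source schemes, builds
    germline-rooted clonal lineage trees by minimum-Levenshtein attachment,
    derives substitution rank and residue-likelihood statistics along tree
    edges, and runs repertoire-level association analyses (isotype, V-gene
    family, somatic hypermutation, clonal expansion, binding affinity).
    Includes a synthetic repertoire generator and a germline-anchored
    likelihood provider so the full pipeline is testable without model
    weights or sequencing data.
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
    withr,
    optparse
Config/testthat/edition: 3
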