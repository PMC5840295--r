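Package: spectracall
Title: Spectral-Count Interactome Scoring and Transfection-Artifact
    Expression Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free AP-MS interactor calling from spectral counts:
    per-run G-tests against pooled controls, replicate fold change and
    Welch t-test, a SAINT-style negative-binomial mixture score, bait-level
    correction factors, consensus interactor calls and domain-deletion
    differential-binding classification, with network export. Also provides
    the RNA-seq side of the workflow: RPKM, a lightweight negative-binomial
    differential-expression test, a transfection-artifact filter cascade,
    endogenous-versus-transgene expression estimation from exon counts, and
    replicate concordance. Includes seeded synthetic-data generators with
    known ground truth for both assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
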