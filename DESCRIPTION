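Package: ohrank
Title: One Health Risk Factor and Disease Prioritisation Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A deterministic engine for co-creation workshops that jointly
    prioritise risk factors for epidemic-prone diseases and the diseases
    themselves from a One Health perspective. Implements the five-step
    multi-criteria decision analysis workflow: vote-based shortlisting of
    candidate risk factors and diseases, criterion weighting from pairwise
    comparisons via the Analytic Hierarchy Process with consistency
    diagnostics, ordinal criterion scoring against three-level rubrics,
    composite risk-impact and disease-burden scores, and min-max normalised
    group-wise and combined rankings with explicit tie reporting. Includes
    delimited-text readers and writers for all workshop artefacts, an
    end-to-end pipeline driver with an auditable run log, a plain-text and
    HTML summary report, a command-line interface, and a seeded synthetic
    workshop generator for testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
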