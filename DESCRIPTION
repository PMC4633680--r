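Package: e3lfq
Title: Label-Free Quantitative Proteomics for E3 Ubiquitin Ligase
    Substrate Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dual-branch label-free quantification (LFQ) pipeline for
    nominating substrates of an E3 ubiquitin ligase from knockout versus
    wild-type peptide-ion intensity data. Implements median-of-ratios
    normalization against a reference run, Top-3 protein abundance index
    (PAI) roll-up, a pairwise-ratio least-squares protein profiling branch,
    completeness and minimum-peptide filtering, per-protein Welch tests with
    fold-change thresholds, and the intersection of both branches into a
    substrate-candidate call with replicate-correlation and absent-marker
    quality control. Ships a seeded spike-in simulator of 3-vs-3
    knockout-versus-wild-type dendritic-cell proteomes so the whole pipeline
    is testable without raw mass-spectrometry data.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
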