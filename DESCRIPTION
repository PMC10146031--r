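Package: iscr
Title: Information Scale Correction for Mixed-Length Amplicon Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Harmonizes amplicon sequencing datasets that target the same
    marker (e.g. the 18S rRNA v4 region) with different primer pairs and
    therefore different amplicon lengths. A nucleotide profile hidden Markov
    model trained on a multiple alignment of the target sub-region locates
    the sub-region in each read by glocal Viterbi alignment and excises it,
    so that all datasets carry the same information scale. The package also
    re-implements the downstream evaluation machinery: dereplication and
    UNOISE-style ASV denoising, abundance-table construction, Bray-Curtis /
    NMDS ordination, Procrustes superimposition with a permutation test, and
    medoid-referenced correction-effectiveness statistics that decide whether
    the correction improved cross-dataset comparability. A seeded simulator
    generates shared communities observed through different primer windows
    for end-to-end testing without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
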