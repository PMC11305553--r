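Package: airrforge
Title: Simulation, Error Correction and Clonal Analysis of Immune Repertoire Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for adaptive immune receptor repertoire
    (AIRR) sequencing analysis. Simulates ground-truth B-cell receptor
    repertoires with clonal structure, somatic hypermutation and UMI-tagged
    Illumina-like paired-end reads with a linear positional error profile;
    re-implements the bulk-sequencing processing chain (quality filtering, UMI
    consensus error correction, pair assembly, duplicate collapsing, V(D)J
    annotation against a synthetic germline reference, alignment quality
    control); infers B- and T-cell clones by single-linkage clustering of
    length-normalized junction Hamming distances with data-driven distance
    thresholds; benchmarks recovered sequences against simulated truth; and
    detects convergent antibody clusters across subjects with
    information-content sequence logos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
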