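Package: wzdiff
Title: Sex Chromosome W/Z Differentiation Analysis
Version: 0.1.0
Authors@R:
    person("wzdiff", "developers", email = "wzdiff@example.org", role = c("aut", "cre"))
Description: Tools to quantify the molecular differentiation of a young
    W/Z sex chromosome pair from assembled chromosome sequences and pooled
    resequencing data. Implements windowed W-Z mutation percentages from
    whole-chromosome alignments (PAF/MAF or a built-in co-linear anchor
    aligner), CpG-adjusted Kimura 2-parameter transposable-element age
    landscapes, pseudogene calling by frameshift or premature stop codon
    with coverage/identity filtering and duplicate-gene clustering,
    sex-specific SNP density from female/male pooled allele counts, and
    centromere/arm karyotype arithmetic, integrated into a per-arm report.
    A fully deterministic synthetic Z/W chromosome-pair generator with
    complete ground truth makes the whole pipeline testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
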