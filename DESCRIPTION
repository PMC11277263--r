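Package: ribopause
Title: Ribosome Pausing Analysis for Ribo-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of ribosome pausing from ribosome
    profiling (Ribo-seq) data in transcript coordinates. Provides P-site offset
    estimation and metagene diagnostics (3-nt periodicity, start/stop profiles),
    sliding-window pause scoring with coverage-binned z-scores and strict
    score/z/depth calling cutoffs, clustering of per-transcript maximum pause
    scores across time points, translation efficiency and the coverage-aware
    translation intensity statistic (median covered depth times fraction of the
    CDS covered), and sequence-feature analyses of pause sites: positional
    nucleotide logos, GC metaplots on absolute and length-scaled axes, nascent
    peptide composition and net charge, position weight matrix scanning with
    exact tail p-values, motif-pausing association tests, and RNA ensemble
    free energy via ViennaRNA. A synthetic-data generator plants pauses,
    motifs, and expression structure with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    mclust,
    testthat (>= 3.0.0),
    yaml
SystemRequirements: ViennaRNA (RNAfold) for ensemble free energy
Config/testthat/edition: 3
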