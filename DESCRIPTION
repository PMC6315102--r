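Package: dieltx
Title: Diel Transcription Analysis for Light/Dark Time-Course Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-genome transcription over light/dark
    (diel) cycles, modelled on microarray studies of marine cyanobacteria.
    Provides diel time-label parsing, probe-to-gene summarization by median
    polish, quantile normalization, signal-to-noise detection calls,
    single-frequency Fourier-score periodicity testing with a seeded
    permutation null and Benjamini-Hochberg FDR control, peak-phase
    hierarchical clustering, Stineman interpolation onto a common time grid,
    reciprocal-best-hit ortholog mapping, cross-organism co-expression
    networks, and an oligonucleotide probe cross-hybridization filter
    cascade. A synthetic-data generator with planted rhythms makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
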