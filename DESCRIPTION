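Package: hadtx
Title: Host-Associated Transcriptome Divergence and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing transcriptome assemblies of insect strains
    maintained on different host plants. Implements reciprocal-best-match
    ortholog pairing with a reference-transcriptome and shared-protein double
    filter, CDS/5'UTR/3'UTR partitioning of transcripts from protein hits,
    per-region sequence divergence, approximate Ka/Ks estimation (Nei-Gojobori
    counting and a kappa-aware Yang-Nielsen-style estimator) with selection
    classification, and count-based differential expression between libraries
    using an MA-plot binomial sampling statistic with trimmed-mean-of-M-values
    normalization and q-values. A codon-level sequence and count simulator
    with recorded ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    BiocGenerics,
    IRanges,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
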