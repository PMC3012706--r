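Package: locustra
Title: Expression Profiling for De Novo Transcriptomes Without a Reference Genome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative expression profiling of de novo
    assembled transcriptomes, built around a 2-phase x 6-stage insect
    developmental design. Implements similarity-based sequence clustering
    for isoform/paralog-aware read counting, TMM library normalization
    with a square-root effective library size and adjusted RPKM values,
    a length- and library-size-normalized Audic-Claverie test for
    differential expression with Benjamini-Hochberg FDR control,
    phase-marker gene screens, GOstat-style term enrichment testing,
    library-level principal component analysis, and assembly quality
    metrics (N50, length bins, reference coverage, chimera flagging).
    Ships a synthetic-data generator with known ground truth that
    emulates the full 12-library design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    IRanges,
    stats,
    utils
Suggests:
    Biostrings,
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
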