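Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for SAGE-style digital gene expression (DGE)
    profiling based on NlaIII/MmeI 21-bp tags: filtering of raw tag reads
    into clean tags, construction of a CATG+17-nt virtual tag library from a
    reference transcriptome, tag-to-gene mapping with at most one mismatch,
    tags-per-million quantification, differential expression by the
    Audic-Claverie exact test with Benjamini-Hochberg false discovery rate
    control, hypergeometric term enrichment, and 2^-ddCt qPCR arithmetic.
    Includes a synthetic tag-read simulator with known expression truth so
    the whole pipeline is exercisable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
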