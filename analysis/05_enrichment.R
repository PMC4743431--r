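#!/usr/bin/env Rscript
# Hypergeometric term enrichment of each treatment's DEG set against the
# simulated annotation, with BH correction per ontology.

source("analysis/00_config.R")

ann <- annotation_table(read.table(file.path(DATA_DIR, "annotation.tsv"),
                                   sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE))

for (key in c("T1_vs_T0", "T2.5_vs_T0")) {
  degs <- read.table(file.path(OUT_DIR, paste0("degs_", key, ".tsv")),
                     sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  called <- degs$gene_id[degs$status != "not_significant"]
  if (length(called) == 0) {
    message(key, ": no DEGs, skipping enrichment")
    next
  }
  res <- enrich(called, ann)
  write.table(as.data.frame(res),
              file.path(OUT_DIR, paste0("enrichment_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  h <- ontology_histogram(res, ann)
  message(sprintf("%s: %d DEGs against %d terms", key, length(called),
                  nrow(res)))
  for (i in seq_len(nrow(h))) {
    message(sprintf("  %s: %d significant terms covering %d DEGs",
                    h$ontology[i], h$n_significant_terms[i], h$n_genes[i]))
  }
}
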