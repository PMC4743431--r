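#!/usr/bin/env Rscript
# Simulate the study: a reference transcriptome, expression truth with
# spiked fold changes, a term annotation, and three artifact-bearing tag
# libraries (T0 control; T1 and T2.5 treated).

source("analysis/00_config.R")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

cfg <- study_synthetic_config()
ref <- generate_reference(cfg)
truth <- generate_truth(cfg, ref)
ann <- generate_annotation(cfg, ref)

write_reference_fasta(ref, file.path(DATA_DIR, "reference.fa"))
write_truth_tsv(truth, file.path(DATA_DIR, "truth.tsv"))
write.table(ann, file.path(DATA_DIR, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("reference: %d transcripts, %d without an eligible CATG site",
                nrow(ref), length(truth$unmappable_gene_ids)))
message(sprintf("truth: %d DE genes (fold changes %s)",
                length(truth$de_gene_ids),
                paste(sort(unique(truth$genes$fold_change[truth$genes$is_de])),
                      collapse = "/")))

for (i in seq_along(LIB_NAMES)) {
  sim <- simulate_tag_reads(ref, truth, cfg, library_id = i)
  write_reads(sim$reads, lib_file("reads", LIB_NAMES[i], "txt"))
  write.table(data.frame(gene_id = names(sim$true_counts),
                         true_count = as.integer(sim$true_counts)),
              lib_file("true_counts", LIB_NAMES[i]), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("library %s: %d raw reads (%d genuine, %d artifacts)",
                  LIB_NAMES[i], length(sim$reads), sum(sim$true_counts),
                  sum(sim$artifact_counts)))
}
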