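#!/usr/bin/env Rscript
# Audic-Claverie differential expression of T1 and T2.5 against T0 at
# FDR <= 0.001 and |log2Ratio| >= 1, with fold-change bins, the DEG-set
# overlap between the two treatments, and recovery against the simulation
# truth.

source("analysis/00_config.R")

ref <- read_reference_fasta(file.path(DATA_DIR, "reference.fa"))
index <- build_index(ref)
truth <- read.table(file.path(DATA_DIR, "truth.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)

expr_of <- function(lib) {
  clean <- read_tag_table(lib_file("clean_tags", lib))
  quantify(map_tags(clean, index), clean, names(ref))
}
expr <- setNames(lapply(LIB_NAMES, expr_of), LIB_NAMES)

deg_sets <- list()
for (treated in c("T1", "T2.5")) {
  degs <- call_degs(expr[["T0"]], expr[[treated]])
  key <- paste0(treated, "_vs_T0")
  write.table(as.data.frame(degs), file.path(OUT_DIR, paste0("degs_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(volcano_table(degs),
              file.path(OUT_DIR, paste0("volcano_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- comparison_summary(degs)
  bins <- summ$fold_change_bins
  message(sprintf("%s: %d tested, %d up, %d down (%d DEGs)", key,
                  summ$n_tested, summ$n_up, summ$n_down, summ$n_deg))
  message(sprintf("  fold changes: %.2f%% < 5-fold, %.2f%% >= 5-fold up, %.2f%% >= 5-fold down",
                  bins$pct[1], bins$pct[2], bins$pct[3]))

  called <- degs$gene_id[degs$status != "not_significant"]
  deg_sets[[key]] <- called
  true_de <- truth$gene_id[truth$is_de]
  message(sprintf("  truth: sensitivity %.2f, false discoveries %d/%d",
                  mean(true_de %in% called),
                  sum(!(called %in% true_de)), length(called)))
}

ov <- compare_deg_sets(deg_sets[[1]], deg_sets[[2]])
message(sprintf("DEG overlap: %d only in T1, %d only in T2.5, %d in both",
                ov$a_only, ov$b_only, ov$overlap))
writeLines(jsonlite::toJSON(
  list(T1_vs_T0 = length(deg_sets[[1]]), T2.5_vs_T0 = length(deg_sets[[2]]),
       overlap = ov$overlap), auto_unbox = TRUE),
  file.path(OUT_DIR, "deg_overlap.json"))
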