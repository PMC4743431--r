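#!/usr/bin/env Rscript
# Emulated qPCR validation: synthesize triplicate Ct measurements for a
# panel of DEGs from their true fold changes (target Ct shifts by
# -log2(fold change); reference gene constant), compute 2^-ddCt relative
# levels against T0, and report concordance with the DGE log2 ratios.

source("analysis/00_config.R")
set.seed(STUDY_SEED + 600)

truth <- read.table(file.path(DATA_DIR, "truth.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
degs <- read.table(file.path(OUT_DIR, "degs_T2.5_vs_T0.tsv"), sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)
called <- degs[degs$status != "not_significant", ]
panel <- head(called$gene_id[order(called$fdr)], 8)
if (length(panel) < 2) stop("not enough DEGs for a validation panel")

fc <- setNames(truth$fold_change, truth$gene_id)[panel]
ct <- do.call(rbind, lapply(panel, function(g) {
  base_ct <- runif(1, 22, 28)
  rbind(
    data.frame(sample_id = "T0", gene_id = g,
               ct_target = base_ct + rnorm(3, 0, 0.1),
               ct_reference = 15 + rnorm(3, 0, 0.1)),
    data.frame(sample_id = "T2.5", gene_id = g,
               ct_target = base_ct - log2(fc[g]) + rnorm(3, 0, 0.1),
               ct_reference = 15 + rnorm(3, 0, 0.1)))
}))
write.table(ct, file.path(DATA_DIR, "qpcr_ct.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

rel <- qpcr_relative_table(ct, control_sample = "T0")
write.table(rel, file.path(OUT_DIR, "qpcr_relative_levels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

dge_l2 <- setNames(degs$log2_ratio, degs$gene_id)[panel]
q_levels <- setNames(rel$relative_level[rel$sample_id == "T2.5"],
                     rel$gene_id[rel$sample_id == "T2.5"])
cc <- concordance(dge_l2, q_levels)
message(sprintf("qPCR panel of %d genes: sign agreement %.2f, Spearman rho %.2f",
                cc$n_genes, cc$sign_agreement, cc$rank_correlation))
writeLines(jsonlite::toJSON(cc, auto_unbox = TRUE),
           file.path(OUT_DIR, "qpcr_concordance.json"))
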