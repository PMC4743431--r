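#!/usr/bin/env Rscript
# Build the virtual tag library from the reference, map each library's
# clean tags (<= 1 mismatch, exact hits first), quantify unambiguous tags
# per gene as TPM, and emit the per-library audit summaries.

source("analysis/00_config.R")

ref <- read_reference_fasta(file.path(DATA_DIR, "reference.fa"))
index <- build_index(ref)
write_index(index, file.path(DATA_DIR, "virtual_tag_index.tsv"))
message(sprintf("virtual tag library: %d distinct tags over %d genes (%d untaggable)",
                length(index$keys), length(index$gene_ids),
                length(index$untaggable_genes)))

# filter stats were serialized as JSON by 02_clean_tags.R
read_filter_stats <- function(lib) {
  s <- jsonlite::read_json(lib_file("filter_stats", lib, "json"),
                           simplifyVector = TRUE)
  structure(s, class = "filter_stats")
}

for (lib in LIB_NAMES) {
  clean <- read_tag_table(lib_file("clean_tags", lib))
  mapping <- map_tags(clean, index)
  expr <- quantify(mapping, clean, names(ref))
  genome <- genome_mapping_stats(clean, unname(ref))
  summ <- library_summary(read_filter_stats(lib), mapping, expr, genome)

  write_mapping_report(mapping, lib_file("mapping", lib))
  write_expression_table(expr, lib_file("expression", lib))
  write_library_summary(summ, lib_file("summary", lib))

  ct <- mapping$counters
  message(sprintf("%s: %.2f%% of distinct clean tags mapped, %.2f%% unambiguous, %.2f%% unknown; %d/%d genes detected (%.2f%%)",
                  lib, summ$all_mapped_distinct_pct,
                  summ$unambiguous_distinct_pct, summ$unknown_distinct_pct,
                  ct$tag_mapped_gene_count, length(ref),
                  summ$unambiguous_gene_pct_of_ref))
}
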