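#!/usr/bin/env Rscript
# Filter raw reads into clean tags (empty -> adaptor -> N -> length ->
# singleton), then summarize the copy-number distribution per library.

source("analysis/00_config.R")

for (lib in LIB_NAMES) {
  reads <- read_reads(lib_file("reads", lib, "txt"))
  res <- clean_tags(reads)
  write_tag_table(res$clean, lib_file("clean_tags", lib))
  jsonlite::write_json(unclass(res$stats),
                       lib_file("filter_stats", lib, "json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("%s: %d raw -> %d clean (%.1f%%), %d distinct (%.1f%% of raw distinct)",
                  lib, res$stats$raw_total, res$stats$clean_total,
                  res$stats$clean_pct_of_raw, res$stats$clean_distinct,
                  res$stats$distinct_clean_pct_of_raw_distinct))

  dist <- copy_number_distribution(res$clean)
  write.table(dist, lib_file("copy_number", lib), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("  copy numbers: %.1f%% of distinct tags at 2-10 copies, %.1f%% at 11-100, %.1f%% above 100",
                  dist$distinct_pct[1], dist$distinct_pct[2],
                  dist$distinct_pct[3]))
}
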