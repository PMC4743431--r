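#' Per-gene quantification from unambiguous tags
#'
#' Sums copy numbers of unambiguous tags per gene and normalizes to TPM
#' (tag copies per million clean tags — a tag-frequency normalization; tags
#' are fixed-length, so no gene-length correction applies). The denominator
#' is the library's total clean tags, not the mapped total, so the TPMs of
#' a library sum to at most one million.
#'
#' A tag that is unambiguous via several sites of one gene contributes its
#' full copy number once.
#'
#' @param mapping a [map_tags()] result produced from `clean`.
#' @param clean the [tag_count_table()] the mapping was computed from.
#' @param reference_genes character vector of all reference gene ids (the
#'   gene universe; genes with no tags appear with count 0).
#' @return a `gene_expression_table`: data.frame with columns `gene_id`,
#'   `raw_count`, `tpm`; attributes `library_clean_total`,
#'   `tag_mapped_gene_count`, `pct_of_ref_genes`.
#' @export
quantify <- function(mapping, clean, reference_genes) {
  stopifnot(inherits(mapping, "mapping_result"),
            inherits(clean, "tag_count_table"),
            is.character(reference_genes), length(reference_genes) > 0,
            !anyDuplicated(reference_genes))
  if (clean$total_tags == 0) stop("empty library: clean total is 0")
  a <- mapping$assignments
  un <- a[a$class == "unambiguous", , drop = FALSE]
  counts <- tapply(un$count, factor(un$gene_id, levels = reference_genes),
                   sum, default = 0L)
  raw_count <- as.integer(counts)
  # conservation: per-gene sums must equal the unambiguous mapped total
  stopifnot(sum(raw_count) == mapping$counters$unambiguous_total)
  out <- data.frame(gene_id = reference_genes,
                    raw_count = raw_count,
                    tpm = 1e6 * raw_count / clean$total_tags,
                    stringsAsFactors = FALSE)
  detected <- sum(raw_count > 0)
  structure(out,
            class = c("gene_expression_table", "data.frame"),
            library_clean_total = clean$total_tags,
            tag_mapped_gene_count = detected,
            pct_of_ref_genes = pct_of(detected, length(reference_genes)))
}

#' Table-1-style per-library summary
#'
#' Combines the cleaning, mapping and quantification statistics of one
#' library into the classic DGE audit table: raw and clean totals and
#' distinct counts, all-mapped and unambiguous totals/distincts with
#' percentages of clean, unknown tags, gene coverage, and (optionally)
#' genome-membership percentages.
#'
#' @param filter_stats the `stats` element of [clean_tags()].
#' @param mapping a [map_tags()] result.
#' @param expression a [quantify()] result.
#' @param genome_stats optional [genome_mapping_stats()] result.
#' @return a `library_summary` list of named numbers; percentages are
#'   unrounded (rounding to 2 decimals happens in the TSV/print output).
#' @export
library_summary <- function(filter_stats, mapping, expression,
                            genome_stats = NULL) {
  stopifnot(inherits(filter_stats, "filter_stats"),
            inherits(mapping, "mapping_result"),
            inherits(expression, "gene_expression_table"))
  ct <- mapping$counters
  if (filter_stats$raw_total == 0) {
    warning("zero-read library: all percentages reported as 0")
  }
  summary_from_counts(
    raw_total = filter_stats$raw_total,
    raw_distinct = filter_stats$raw_distinct,
    clean_total = filter_stats$clean_total,
    clean_distinct = filter_stats$clean_distinct,
    all_mapped_total = ct$all_mapped_total,
    all_mapped_distinct = ct$all_mapped_distinct,
    unambiguous_total = ct$unambiguous_total,
    unambiguous_distinct = ct$unambiguous_distinct,
    unknown_total = ct$unknown_total,
    unknown_distinct = ct$unknown_distinct,
    all_gene_count = ct$all_gene_count,
    unambiguous_gene_count = ct$tag_mapped_gene_count,
    reference_gene_count = nrow(expression),
    genome_mapped_total = if (is.null(genome_stats)) NA_real_
      else genome_stats$mapped_total,
    genome_mapped_distinct = if (is.null(genome_stats)) NA_real_
      else genome_stats$mapped_distinct)
}

#' Library summary percentages from bare counts
#'
#' The percentage-computation path shared by [library_summary()] and by
#' replication of published library statistics: given the raw counts of a
#' DGE audit table, computes every derived percentage.
#'
#' @param raw_total,raw_distinct raw tag copies and distinct raw tags.
#' @param clean_total,clean_distinct clean tag copies and distinct clean
#'   tags.
#' @param all_mapped_total,all_mapped_distinct tags mapped to any gene.
#' @param unambiguous_total,unambiguous_distinct tags mapped to exactly one
#'   gene.
#' @param unknown_total,unknown_distinct tags mapped to no gene.
#' @param all_gene_count,unambiguous_gene_count genes hit by any /
#'   unambiguous tags.
#' @param reference_gene_count size of the reference gene set.
#' @param genome_mapped_total,genome_mapped_distinct genome-membership
#'   counts (NA if not computed).
#' @return a `library_summary` list: the input counts plus
#'   `clean_pct_of_raw`, `distinct_clean_pct_of_raw_distinct`,
#'   `all_mapped_total_pct`, `all_mapped_distinct_pct`,
#'   `unambiguous_total_pct`, `unambiguous_distinct_pct`,
#'   `unknown_total_pct`, `unknown_distinct_pct`, `genome_total_pct`,
#'   `genome_distinct_pct`, `all_gene_pct_of_ref`,
#'   `unambiguous_gene_pct_of_ref` (percentages of clean totals / distinct
#'   clean / reference genes as appropriate; unrounded).
#' @export
summary_from_counts <- function(raw_total, raw_distinct,
                                clean_total, clean_distinct,
                                all_mapped_total = NA_real_,
                                all_mapped_distinct = NA_real_,
                                unambiguous_total = NA_real_,
                                unambiguous_distinct = NA_real_,
                                unknown_total = NA_real_,
                                unknown_distinct = NA_real_,
                                all_gene_count = NA_real_,
                                unambiguous_gene_count = NA_real_,
                                reference_gene_count = NA_real_,
                                genome_mapped_total = NA_real_,
                                genome_mapped_distinct = NA_real_) {
  p <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else pct_of(a, b)
  structure(list(
    raw_total = raw_total, raw_distinct = raw_distinct,
    clean_total = clean_total, clean_distinct = clean_distinct,
    all_mapped_total = all_mapped_total,
    all_mapped_distinct = all_mapped_distinct,
    unambiguous_total = unambiguous_total,
    unambiguous_distinct = unambiguous_distinct,
    unknown_total = unknown_total, unknown_distinct = unknown_distinct,
    all_gene_count = all_gene_count,
    unambiguous_gene_count = unambiguous_gene_count,
    reference_gene_count = reference_gene_count,
    genome_mapped_total = genome_mapped_total,
    genome_mapped_distinct = genome_mapped_distinct,
    clean_pct_of_raw = p(clean_total, raw_total),
    distinct_clean_pct_of_raw_distinct = p(clean_distinct, raw_distinct),
    all_mapped_total_pct = p(all_mapped_total, clean_total),
    all_mapped_distinct_pct = p(all_mapped_distinct, clean_distinct),
    unambiguous_total_pct = p(unambiguous_total, clean_total),
    unambiguous_distinct_pct = p(unambiguous_distinct, clean_distinct),
    unknown_total_pct = p(unknown_total, clean_total),
    unknown_distinct_pct = p(unknown_distinct, clean_distinct),
    genome_total_pct = p(genome_mapped_total, clean_total),
    genome_distinct_pct = p(genome_mapped_distinct, clean_distinct),
    all_gene_pct_of_ref = p(all_gene_count, reference_gene_count),
    unambiguous_gene_pct_of_ref = p(unambiguous_gene_count,
                                    reference_gene_count)
  ), class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  df <- as.data.frame.library_summary(x)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.library_summary <- function(x, ...) {
  nm <- names(x)
  val <- unlist(x)
  is_pct <- grepl("pct", nm)
  data.frame(statistic = nm,
             value = ifelse(is_pct, round(val, 2), val),
             stringsAsFactors = FALSE)
}

#' Write per-library expression and summary outputs
#'
#' @param expression a [quantify()] result.
#' @param path TSV path (gene_id, raw_count, tpm).
#' @return the path, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  stopifnot(inherits(expression, "gene_expression_table"))
  write_tsv(as.data.frame(expression), path)
}

#' @param summary a `library_summary`.
#' @rdname write_expression_table
#' @export
write_library_summary <- function(summary, path) {
  stopifnot(inherits(summary, "library_summary"))
  write_tsv(as.data.frame(summary), path)
}
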