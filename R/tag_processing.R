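#' Tag count tables
#'
#' A `tag_count_table` holds distinct tag sequences with integer copy
#' numbers plus the library totals. After cleaning, every tag has length 21,
#' copy number >= 2 and no N.
#'
#' @param tags character vector of distinct tag sequences.
#' @param counts integer copy numbers, same length as `tags`.
#' @return a `tag_count_table`: list with `tag`, `count` (sorted by
#'   descending count then tag), `total_tags`, `distinct_tags`.
#' @export
tag_count_table <- function(tags = character(0), counts = integer(0)) {
  tags <- as.character(tags)
  counts <- as.integer(counts)
  stopifnot(length(tags) == length(counts), !anyDuplicated(tags),
            all(counts >= 1))
  ord <- order(-counts, tags)
  structure(list(tag = tags[ord],
                 count = as.integer(counts[ord]),
                 total_tags = as.integer(sum(counts)),
                 distinct_tags = length(tags)),
            class = "tag_count_table")
}

#' @export
print.tag_count_table <- function(x, ...) {
  cat("Tag count table:", x$distinct_tags, "distinct tags,",
      x$total_tags, "total copies\n")
  invisible(x)
}

#' Filter raw tag reads into clean tags
#'
#' Applies the DGE cleaning filters in a fixed order so every removed read
#' is counted in exactly one category: empty reads, adaptor reads (exact
#' prefix match against `adaptor_sequences`), low-quality reads (containing
#' "N"), abnormal-length reads (length != `tag_length`); the survivors are
#' collapsed to distinct tags and tags with copy number < 2 (singletons) are
#' removed. What remains are the clean tags.
#'
#' @param raw_reads character vector of raw reads.
#' @param adaptor_sequences adaptor strings for prefix detection.
#' @param tag_length expected tag length (CATG + 17 nt = 21).
#' @return list with `clean` (a [tag_count_table()]) and `stats` (a
#'   `filter_stats` list: raw/removed/clean totals and distinct counts plus
#'   clean-percentage fields).
#' @export
clean_tags <- function(raw_reads, adaptor_sequences = dge_default_adaptors(),
                       tag_length = 21L) {
  if (tag_length < 5) stop("tag_length must be >= 5 (CATG + at least 1 nt)")
  raw_total <- length(raw_reads)
  raw_distinct <- length(unique(raw_reads))

  remaining <- raw_reads
  is_empty <- !nzchar(remaining)
  removed_empty <- sum(is_empty)
  remaining <- remaining[!is_empty]

  is_adaptor <- rep(FALSE, length(remaining))
  for (ad in adaptor_sequences) {
    is_adaptor <- is_adaptor | startsWith(remaining, ad)
  }
  removed_adaptor <- sum(is_adaptor)
  remaining <- remaining[!is_adaptor]

  has_n <- grepl("N", remaining, fixed = TRUE)
  removed_low_quality <- sum(has_n)
  remaining <- remaining[!has_n]

  abnormal <- nchar(remaining) != tag_length
  removed_abnormal <- sum(abnormal)
  remaining <- remaining[!abnormal]

  counts <- table(remaining)
  singles <- counts < 2
  removed_singletons <- sum(counts[singles])
  counts <- counts[!singles]

  clean <- tag_count_table(names(counts), as.integer(counts))
  stats <- structure(list(
    raw_total = raw_total,
    raw_distinct = raw_distinct,
    removed_empty = as.integer(removed_empty),
    removed_adaptor = as.integer(removed_adaptor),
    removed_low_quality = as.integer(removed_low_quality),
    removed_abnormal_length = as.integer(removed_abnormal),
    removed_singletons = as.integer(removed_singletons),
    clean_total = clean$total_tags,
    clean_distinct = clean$distinct_tags,
    clean_pct_of_raw = pct_of(clean$total_tags, raw_total),
    distinct_clean_pct_of_raw_distinct = pct_of(clean$distinct_tags,
                                                raw_distinct)
  ), class = "filter_stats")
  list(clean = clean, stats = stats)
}

#' Copy-number distribution of clean tags
#'
#' Bins the clean tag table by copy number and reports, per bin, the
#' percentage of total tag copies and of distinct tags — the classic
#' low/medium/high expression breakdown (e.g. bins `[2,10]`, `[11,100]`,
#' `[101,Inf]`).
#'
#' @param table a [tag_count_table()].
#' @param bins list of `c(lo, hi)` pairs partitioning `[2, Inf)`; `hi` may
#'   be `Inf`.
#' @return data.frame with columns `bin`, `lo`, `hi`, `total_count`,
#'   `distinct_count`, `total_pct`, `distinct_pct`.
#' @export
copy_number_distribution <- function(table,
                                     bins = list(c(2, 10), c(11, 100),
                                                 c(101, Inf))) {
  stopifnot(inherits(table, "tag_count_table"))
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  if (lo[1] != 2 || !is.infinite(hi[length(hi)]) ||
      any(hi < lo) ||
      (length(lo) > 1 && any(lo[-1] != hi[-length(hi)] + 1))) {
    stop("bins must partition [2, Inf) without gaps or overlaps")
  }
  idx <- findInterval(table$count, lo)
  total_count <- vapply(seq_along(lo), function(b) {
    sum(table$count[idx == b])
  }, numeric(1))
  distinct_count <- vapply(seq_along(lo), function(b) {
    sum(idx == b)
  }, numeric(1))
  data.frame(
    bin = sprintf("%g-%g", lo, hi),
    lo = lo, hi = hi,
    total_count = total_count,
    distinct_count = distinct_count,
    total_pct = if (table$total_tags > 0)
      100 * total_count / table$total_tags else rep(0, length(lo)),
    distinct_pct = if (table$distinct_tags > 0)
      100 * distinct_count / table$distinct_tags else rep(0, length(lo)),
    stringsAsFactors = FALSE)
}

#' Write / read a tag count table as TSV
#'
#' Columns `tag`, `count`, sorted by descending count then tag.
#'
#' @param table a [tag_count_table()].
#' @param path file path.
#' @return `write_tag_table`: the path, invisibly. `read_tag_table`: a
#'   [tag_count_table()].
#' @export
write_tag_table <- function(table, path) {
  stopifnot(inherits(table, "tag_count_table"))
  write_tsv(data.frame(tag = table$tag, count = table$count), path)
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  df <- read_tsv(path, colClasses = c("character", "integer"))
  tag_count_table(df$tag, df$count)
}

#' @export
print.filter_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Raw: %d (%d distinct)\n",
           "Removed: %d empty, %d adaptor, %d N-containing, ",
           "%d abnormal-length, %d singleton copies\n",
           "Clean: %d (%.1f%% of raw), %d distinct (%.1f%% of raw distinct)\n"),
    x$raw_total, x$raw_distinct, x$removed_empty, x$removed_adaptor,
    x$removed_low_quality, x$removed_abnormal_length, x$removed_singletons,
    x$clean_total, x$clean_pct_of_raw, x$clean_distinct,
    x$distinct_clean_pct_of_raw_distinct))
  invisible(x)
}
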