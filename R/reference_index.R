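#' Build a virtual tag library from reference transcripts
#'
#' Exhaustively extracts every CATG + 17-nt 21-mer from the reference: a
#' 21-mer is an index key iff it occurs at an eligible site (CATG anchor
#' with 17 nt downstream, window free of N) under the chosen mode and
#' strand policy. Site ranks count from the 3' end (rank 0 = 3'-most),
#' because MmeI libraries favour the 3'-most site.
#'
#' @param reference named character vector or data.frame(gene_id, sequence);
#'   duplicate gene ids are an error.
#' @param mode `"all_sites"` keeps every eligible site; `"three_prime_most"`
#'   keeps only the 3'-most sense-strand site per gene.
#' @param strand_policy `"sense_only"` (the protocol sequences the sense
#'   strand) or `"both_strands"` (also index tags on the reverse
#'   complement).
#' @return a `virtual_tag_index`: list with `table` (data.frame tag,
#'   gene_id, position, rank, strand), `keys`, `genes_by_key` (per-key
#'   unique gene sets), `untaggable_genes`, `gene_ids`, `mode`,
#'   `strand_policy`.
#' @export
build_index <- function(reference,
                        mode = c("all_sites", "three_prime_most"),
                        strand_policy = c("sense_only", "both_strands")) {
  mode <- match.arg(mode)
  strand_policy <- match.arg(strand_policy)
  seqs <- as_reference_vector(reference)
  if (anyDuplicated(names(seqs))) stop("duplicate gene_id in reference")

  per_gene <- lapply(names(seqs), function(g) {
    s <- tag_sites(seqs[[g]])
    if (nrow(s) == 0) return(NULL)
    if (mode == "three_prime_most") s <- s[s$rank == 0L, , drop = FALSE]
    data.frame(tag = s$tag, gene_id = g, position = s$position,
               rank = s$rank, strand = "+", stringsAsFactors = FALSE)
  })
  if (strand_policy == "both_strands") {
    rc <- reverse_complement(unname(seqs))
    per_gene_rc <- lapply(seq_along(seqs), function(i) {
      s <- tag_sites(rc[i])
      if (nrow(s) == 0) return(NULL)
      data.frame(tag = s$tag, gene_id = names(seqs)[i],
                 position = s$position, rank = s$rank, strand = "-",
                 stringsAsFactors = FALSE)
    })
    per_gene <- c(per_gene, per_gene_rc)
  }
  tab <- do.call(rbind, per_gene)
  if (is.null(tab)) {
    tab <- data.frame(tag = character(0), gene_id = character(0),
                      position = integer(0), rank = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  }
  genes_by_key <- lapply(split(tab$gene_id, tab$tag), unique)
  tagged <- unique(tab$gene_id[tab$strand == "+" |
                                 strand_policy == "both_strands"])
  structure(list(table = tab,
                 keys = names(genes_by_key),
                 genes_by_key = genes_by_key,
                 untaggable_genes = setdiff(names(seqs), unique(tab$gene_id)),
                 gene_ids = names(seqs),
                 mode = mode,
                 strand_policy = strand_policy),
            class = "virtual_tag_index")
}

#' @export
print.virtual_tag_index <- function(x, ...) {
  cat("Virtual tag index:", length(x$keys), "distinct tags over",
      length(x$gene_ids), "genes (", x$mode, ",", x$strand_policy, ")\n")
  if (length(x$untaggable_genes) > 0) {
    cat(" ", length(x$untaggable_genes), "genes without an eligible site\n")
  }
  invisible(x)
}

#' Enumerate Hamming-distance-1 neighbours of tags
#'
#' Every 21-mer over A/C/G/T has exactly 63 distance-1 neighbours
#' (21 positions x 3 alternative bases).
#'
#' @param tags character vector of equal-length DNA strings.
#' @param positions positions where a mismatch is allowed (default: all).
#' @return data.frame with columns `tag_idx` (index into `tags`) and
#'   `neighbor`.
#' @export
hamming1_neighbors <- function(tags, positions = NULL) {
  if (length(tags) == 0) {
    return(data.frame(tag_idx = integer(0), neighbor = character(0)))
  }
  L <- nchar(tags[1])
  stopifnot(all(nchar(tags) == L))
  if (is.null(positions)) positions <- seq_len(L)
  out_idx <- vector("list", length(positions) * 3L)
  out_nb <- vector("list", length(positions) * 3L)
  k <- 0L
  for (p in positions) {
    cur <- substring(tags, p, p)
    for (j in 1:3) {
      new <- .BASE_ALT[cbind(match(cur, DNA_BASES), j)]
      nb <- tags
      substr(nb, p, p) <- new
      k <- k + 1L
      out_idx[[k]] <- seq_along(tags)
      out_nb[[k]] <- nb
    }
  }
  data.frame(tag_idx = unlist(out_idx), neighbor = unlist(out_nb),
             stringsAsFactors = FALSE)
}

#' Map clean tags to genes with at most one mismatch
#'
#' Exact matches take priority: if a clean tag is itself an index key its
#' gene set is that key's genes; otherwise (when `max_mismatch = 1`) the
#' gene sets of all Hamming-distance-1 neighbours that are keys are
#' unioned. Ambiguity is decided at the gene level — a tag hitting several
#' sites of the same gene is unambiguous. |gene set| = 1 gives class
#' `unambiguous`, > 1 `ambiguous`, 0 `unknown`.
#'
#' @param clean a [tag_count_table()] of clean tags (all length 21).
#' @param index a [build_index()] result.
#' @param max_mismatch 0 or 1.
#' @param mismatch_positions optional restriction of mismatch positions
#'   (e.g. `5:21` to keep the CATG anchor exact); default allows all 21.
#' @return a `mapping_result`: list with `assignments` (data.frame tag,
#'   count, class, gene_id, matched_via) and `counters` (all-mapped /
#'   unambiguous / ambiguous / unknown totals and distinct counts,
#'   `tag_mapped_gene_count` = genes with at least one unambiguous tag,
#'   `all_gene_count` = genes hit by any mapped tag).
#' @export
map_tags <- function(clean, index, max_mismatch = 1L,
                     mismatch_positions = NULL) {
  stopifnot(inherits(clean, "tag_count_table"),
            inherits(index, "virtual_tag_index"),
            max_mismatch %in% c(0L, 1L))
  tags <- clean$tag
  if (length(tags) > 0 && any(nchar(tags) != TAG_LENGTH)) {
    stop("clean tags must all have length ", TAG_LENGTH,
         " (upstream cleaning bug)")
  }
  n <- length(tags)
  gene_sets <- vector("list", n)
  matched_via <- rep(NA_character_, n)

  exact <- match(tags, index$keys)
  hit <- !is.na(exact)
  gene_sets[hit] <- index$genes_by_key[exact[hit]]
  matched_via[hit] <- "exact"

  if (max_mismatch >= 1L && any(!hit)) {
    todo <- which(!hit)
    nb <- hamming1_neighbors(tags[todo], positions = mismatch_positions)
    m <- match(nb$neighbor, index$keys)
    ok <- !is.na(m)
    if (any(ok)) {
      hits_by_tag <- split(m[ok], nb$tag_idx[ok])
      for (nm in names(hits_by_tag)) {
        i <- todo[as.integer(nm)]
        gene_sets[[i]] <- unique(unlist(
          index$genes_by_key[hits_by_tag[[nm]]], use.names = FALSE))
        matched_via[i] <- "one_mismatch"
      }
    }
  }

  n_genes <- lengths(gene_sets)
  class_ <- ifelse(n_genes == 0, "unknown",
                   ifelse(n_genes == 1, "unambiguous", "ambiguous"))
  gene_id <- rep(NA_character_, n)
  gene_id[n_genes == 1] <- unlist(gene_sets[n_genes == 1], use.names = FALSE)

  assignments <- data.frame(tag = tags, count = clean$count, class = class_,
                            gene_id = gene_id, matched_via = matched_via,
                            stringsAsFactors = FALSE)
  counters <- mapping_counters(assignments, gene_sets, clean)
  structure(list(assignments = assignments, counters = counters,
                 gene_sets = gene_sets),
            class = "mapping_result")
}

mapping_counters <- function(a, gene_sets, clean) {
  mapped <- a$class != "unknown"
  unamb <- a$class == "unambiguous"
  ambig <- a$class == "ambiguous"
  counters <- list(
    clean_total = clean$total_tags,
    clean_distinct = clean$distinct_tags,
    all_mapped_total = sum(a$count[mapped]),
    all_mapped_distinct = sum(mapped),
    unambiguous_total = sum(a$count[unamb]),
    unambiguous_distinct = sum(unamb),
    ambiguous_total = sum(a$count[ambig]),
    ambiguous_distinct = sum(ambig),
    unknown_total = sum(a$count[!mapped]),
    unknown_distinct = sum(!mapped),
    tag_mapped_gene_count = length(unique(a$gene_id[unamb])),
    all_gene_count = length(unique(unlist(gene_sets, use.names = FALSE)))
  )
  # classification trichotomy, asserted on every run
  stopifnot(counters$unambiguous_distinct + counters$ambiguous_distinct +
              counters$unknown_distinct == counters$clean_distinct,
            counters$unambiguous_distinct <= counters$all_mapped_distinct)
  counters
}

#' @export
print.mapping_result <- function(x, ...) {
  ct <- x$counters
  cat(sprintf(paste0(
    "Mapped %d/%d distinct clean tags (%.2f%%); unambiguous %d (%.2f%%), ",
    "unknown %d (%.2f%%); %d genes with unambiguous tags\n"),
    ct$all_mapped_distinct, ct$clean_distinct,
    pct_of(ct$all_mapped_distinct, ct$clean_distinct),
    ct$unambiguous_distinct, pct_of(ct$unambiguous_distinct, ct$clean_distinct),
    ct$unknown_distinct, pct_of(ct$unknown_distinct, ct$clean_distinct),
    ct$tag_mapped_gene_count))
  invisible(x)
}

#' Genome-membership mapping statistics
#'
#' A membership test, not an aligner: a clean tag counts as genome-mapped
#' iff its 21-mer (or, with `max_mismatch = 1`, one of its 63 distance-1
#' variants) occurs anywhere on either strand of any supplied genome
#' sequence.
#'
#' @param clean a [tag_count_table()].
#' @param genome_sequences character vector of genome sequences.
#' @param max_mismatch 0 or 1.
#' @return list with `mapped_total`, `mapped_distinct`,
#'   `mapped_total_pct`, `mapped_distinct_pct`.
#' @export
genome_mapping_stats <- function(clean, genome_sequences, max_mismatch = 1L) {
  stopifnot(inherits(clean, "tag_count_table"), max_mismatch %in% c(0L, 1L))
  kmers <- unique(c(genome_kmers(genome_sequences),
                    genome_kmers(reverse_complement(genome_sequences))))
  tags <- clean$tag
  mapped <- tags %in% kmers
  if (max_mismatch >= 1L && any(!mapped)) {
    todo <- which(!mapped)
    nb <- hamming1_neighbors(tags[todo])
    ok <- nb$neighbor %in% kmers
    mapped[todo[unique(nb$tag_idx[ok])]] <- TRUE
  }
  list(mapped_total = sum(clean$count[mapped]),
       mapped_distinct = sum(mapped),
       mapped_total_pct = pct_of(sum(clean$count[mapped]), clean$total_tags),
       mapped_distinct_pct = pct_of(sum(mapped), clean$distinct_tags))
}

genome_kmers <- function(seqs, k = TAG_LENGTH) {
  out <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  })
  unlist(out, use.names = FALSE)
}

#' Serialize / read a virtual tag index
#'
#' TSV body (tag, gene_id, position, rank, strand) preceded by a JSON
#' header line (prefixed `#`) recording mode and strand policy.
#'
#' @param index a `virtual_tag_index`.
#' @param path file path.
#' @return `write_index`: the path, invisibly. `read_index` is not provided;
#'   rebuild from the reference, which is cheap and exact.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "virtual_tag_index"))
  hdr <- paste0("#", jsonlite::toJSON(
    list(mode = index$mode, strand_policy = index$strand_policy,
         n_genes = length(index$gene_ids),
         untaggable_genes = index$untaggable_genes),
    auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(index$table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mapping report as TSV
#'
#' @param mapping a `mapping_result`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_mapping_report <- function(mapping, path) {
  stopifnot(inherits(mapping, "mapping_result"))
  write_tsv(mapping$assignments, path)
}
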