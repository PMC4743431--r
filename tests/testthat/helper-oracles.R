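# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (brute force, enumeration, textbook definitions) so
# they share no code with the implementation they check.

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# quadratic brute-force tag classification against an index: for each tag,
# compare against every key character by character, prefer exact hits,
# else collect genes of all distance-1 keys
brute_force_map <- function(tags, keys, genes_by_key) {
  keymat <- do.call(rbind, strsplit(keys, ""))
  vapply(tags, function(tg) {
    chars <- strsplit(tg, "")[[1]]
    d <- rowSums(keymat != matrix(chars, nrow = length(keys),
                                  ncol = length(chars), byrow = TRUE))
    genes <- if (any(d == 0)) {
      genes_by_key[[which(d == 0)[1]]]
    } else {
      unique(unlist(genes_by_key[d == 1], use.names = FALSE))
    }
    ng <- length(genes)
    if (ng == 0) "unknown" else if (ng == 1) "unambiguous" else "ambiguous"
  }, character(1))
}

# textbook step-up BH, written from the definition
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# exhaustive hypergeometric upper tail: enumerate every draw of n from N
# with M marked genes, count draws with >= m marked
hyper_enum <- function(m, n, M, N) {
  if (m == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  marked <- seq_len(M)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= m)
}

# negative-binomial form of the Audic-Claverie conditional distribution:
# an independent route through stats::pnbinom
ac_tails_nbinom <- function(x, y, n1, n2) {
  prob <- n1 / (n1 + n2)
  c(lower = pnbinom(y, size = x + 1, prob = prob),
    upper = if (y == 0) 1 else
      pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE))
}

ac_two_sided_oracle <- function(x, y, n1, n2) {
  t <- ac_tails_nbinom(x, y, n1, n2)
  min(1, 2 * min(t))
}

random_tag <- function(n = 1, len = 21) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# minimal expression table for count-level DE tests
expr_from_counts <- function(counts, clean_total, gene_ids = names(counts)) {
  structure(data.frame(gene_id = gene_ids,
                       raw_count = as.integer(counts),
                       tpm = 1e6 * counts / clean_total,
                       stringsAsFactors = FALSE),
            class = c("gene_expression_table", "data.frame"),
            library_clean_total = clean_total,
            tag_mapped_gene_count = sum(counts > 0),
            pct_of_ref_genes = 100 * mean(counts > 0))
}

small_config <- function(...) {
  synthetic_config(n_genes = 40, transcript_length_range = c(100, 400),
                   library_depth = 5000, seed = 7, ...)
}
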