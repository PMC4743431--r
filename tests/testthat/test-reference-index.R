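tag_a <- paste0("CATG", strrep("A", 17))

test_that("index extraction follows the CATG + 17-nt rule", {
  g1 <- paste0("TTT", tag_a)
  idx <- build_index(c(G1 = g1))
  expect_equal(idx$keys, tag_a)
  expect_equal(idx$table$position, 3L)
  expect_equal(idx$table$rank, 0L)
  expect_equal(idx$genes_by_key[[tag_a]], "G1")

  # no CATG at all -> untaggable
  idx <- build_index(c(G1 = strrep("A", 50)))
  expect_length(idx$keys, 0)
  expect_equal(idx$untaggable_genes, "G1")

  # CATG with < 17 nt downstream is skipped
  idx <- build_index(c(G1 = paste0(strrep("T", 10), "CATG", strrep("A", 10))))
  expect_length(idx$keys, 0)

  # a site whose 17-nt window contains N is skipped
  idx <- build_index(c(G1 = paste0("CATGN", strrep("A", 16))))
  expect_length(idx$keys, 0)

  # two genes sharing a tag -> key maps to both
  idx <- build_index(c(G1 = g1, G2 = paste0("CC", tag_a)))
  expect_setequal(idx$genes_by_key[[tag_a]], c("G1", "G2"))

  expect_error(build_index(c(G1 = g1, G1 = g1)), "duplicate")
})

test_that("site ranks count from the 3' end and modes restrict sites", {
  two_sites <- paste0(tag_a, "TT", "CATG", strrep("C", 17))
  idx <- build_index(c(G1 = two_sites))
  tab <- idx$table[order(idx$table$position), ]
  expect_equal(tab$rank, c(1L, 0L))  # downstream site is rank 0
  idx3p <- build_index(c(G1 = two_sites), mode = "three_prime_most")
  expect_equal(nrow(idx3p$table), 1L)
  expect_equal(idx3p$table$rank, 0L)
  expect_equal(idx3p$table$position, 23L)
})

test_that("both_strands indexes tags on the reverse complement too", {
  g <- paste0("TT", tag_a, "GG")
  rc_tag_site <- reverse_complement(g)  # contains CATT..? build and compare
  idx_s <- build_index(c(G1 = g), strand_policy = "sense_only")
  idx_b <- build_index(c(G1 = g), strand_policy = "both_strands")
  expect_gte(length(idx_b$keys), length(idx_s$keys))
  expect_true(all(idx_s$keys %in% idx_b$keys))
  expect_true(all(startsWith(idx_b$keys, "CATG")))
})

test_that("every 21-mer has exactly 63 distance-1 neighbors", {
  set.seed(5)
  tags <- random_tag(4)
  nb <- hamming1_neighbors(tags)
  for (i in seq_along(tags)) {
    mine <- nb$neighbor[nb$tag_idx == i]
    expect_length(mine, 63)
    expect_length(unique(mine), 63)
    expect_true(all(vapply(mine, hamming, numeric(1), a = tags[i]) == 1))
  }
})

test_that("mapping classifies exact, one-mismatch, ambiguous and unknown", {
  t1 <- tag_a
  t2 <- paste0("CATG", strrep("C", 17))
  idx <- build_index(c(G1 = t1, G2 = t2))

  # exact hit
  clean <- tag_count_table(t1, 5L)
  mp <- map_tags(clean, idx)
  a <- mp$assignments
  expect_equal(a$class, "unambiguous")
  expect_equal(a$gene_id, "G1")
  expect_equal(a$matched_via, "exact")

  # one mismatch from G1's tag only
  t1_mm <- paste0("CATG", "T", strrep("A", 16))
  mp <- map_tags(tag_count_table(t1_mm, 4L), idx)
  expect_equal(mp$assignments$class, "unambiguous")
  expect_equal(mp$assignments$gene_id, "G1")
  expect_equal(mp$assignments$matched_via, "one_mismatch")

  # distance >= 2 from every key -> unknown
  t_far <- paste0("CATG", "TT", strrep("A", 15))
  mp <- map_tags(tag_count_table(t_far, 2L), idx)
  expect_equal(mp$assignments$class, "unknown")

  # equidistant from two genes' tags -> ambiguous
  g1 <- paste0("CATGA", strrep("G", 16))
  g2 <- paste0("CATGC", strrep("G", 16))
  idx2 <- build_index(c(G1 = g1, G2 = g2))
  probe <- paste0("CATGT", strrep("G", 16))
  mp <- map_tags(tag_count_table(probe, 2L), idx2)
  expect_equal(mp$assignments$class, "ambiguous")
  expect_true(is.na(mp$assignments$gene_id))

  # a tag hitting two sites of the SAME gene stays unambiguous
  idx3 <- build_index(c(G1 = paste0(g1, "TT", g2)))
  mp <- map_tags(tag_count_table(probe, 2L), idx3)
  expect_equal(mp$assignments$class, "unambiguous")
  expect_equal(mp$assignments$gene_id, "G1")

  # exact-over-mismatch priority: a perfect hit ignores near-neighbors
  mp <- map_tags(tag_count_table(g1, 2L), idx2)
  expect_equal(mp$assignments$class, "unambiguous")
  expect_equal(mp$assignments$matched_via, "exact")

  # malformed tag length is an upstream contract violation
  bad <- tag_count_table("CATGAA", 3L)
  expect_error(map_tags(bad, idx), "length")
})

test_that("map_tags agrees tag-for-tag with quadratic brute force", {
  set.seed(202)
  for (rep_i in 1:5) {
    n_genes <- 30
    seqs <- vapply(seq_len(n_genes), function(i) {
      paste0(paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = ""), "CATG",
             paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE),
                   collapse = ""))
    }, character(1))
    names(seqs) <- sprintf("G%02d", seq_len(n_genes))
    idx <- build_index(seqs)
    # probes: real tags, mutated tags, random tags
    probes <- unique(c(sample(idx$keys, 10, replace = TRUE),
                       vapply(sample(idx$keys, 10, replace = TRUE),
                              function(t) {
                                p <- sample(21, 1)
                                substr(t, p, p) <-
                                  sample(setdiff(c("A", "C", "G", "T"),
                                                 substr(t, p, p)), 1)
                                t
                              }, character(1)),
                       random_tag(10)))
    clean <- tag_count_table(probes, rep(2L, length(probes)))
    mp <- map_tags(clean, idx)
    expected <- brute_force_map(mp$assignments$tag, idx$keys,
                                idx$genes_by_key)
    expect_identical(mp$assignments$class, unname(expected))
    # trichotomy
    ct <- mp$counters
    expect_equal(ct$unambiguous_distinct + ct$ambiguous_distinct +
                   ct$unknown_distinct, ct$clean_distinct)
  }
})

test_that("raising max_mismatch from 0 to 1 never decreases mapped counts", {
  set.seed(77)
  cfg <- small_config(error_rate = 0.05)
  ref <- generate_reference(cfg)
  tr <- generate_truth(cfg, ref)
  sim <- simulate_tag_reads(ref, tr, cfg, 1)
  clean <- clean_tags(sim$reads)$clean
  idx <- build_index(ref)
  m0 <- map_tags(clean, idx, max_mismatch = 0L)
  m1 <- map_tags(clean, idx, max_mismatch = 1L)
  expect_gte(m1$counters$all_mapped_distinct, m0$counters$all_mapped_distinct)
  expect_gte(m1$counters$all_mapped_total, m0$counters$all_mapped_total)
})

test_that("genome membership equals an exhaustive substring scan", {
  # tags drawn from the transcripts with no errors all map
  cfg <- small_config(error_rate = 0,
                      artifact_rates = list(adaptor_only = 0, contains_N = 0,
                                            abnormal_length = 0, empty = 0))
  ref <- generate_reference(cfg)
  tr <- generate_truth(cfg, ref)
  sim <- simulate_tag_reads(ref, tr, cfg, 1)
  clean <- clean_tags(sim$reads)$clean
  gs <- genome_mapping_stats(clean, ref$sequence)
  expect_equal(gs$mapped_distinct_pct, 100)

  # empty genome -> 0%
  gs0 <- genome_mapping_stats(clean, character(0))
  expect_equal(gs0$mapped_distinct_pct, 0)

  # random tags vs a small random genome: oracle = grepl substring scan
  set.seed(13)
  genome <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  tags <- c(random_tag(20), substring(genome, 101, 121),
            substring(genome, 500, 520))
  tags <- unique(tags)
  clean <- tag_count_table(tags, rep(2L, length(tags)))
  gs <- genome_mapping_stats(clean, genome, max_mismatch = 0L)
  rc <- reverse_complement(genome)
  oracle <- vapply(clean$tag, function(t) {
    grepl(t, genome, fixed = TRUE) || grepl(t, rc, fixed = TRUE)
  }, logical(1))
  expect_equal(gs$mapped_distinct, sum(oracle))
})
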