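#' Configuration for the synthetic DGE study
#'
#' Bundles every knob of the synthetic-data generator: a reference
#' transcriptome, per-gene expression truth, and artifact-bearing 21-bp tag
#' reads (NlaIII CATG anchor + 17 nt) for a configurable number of libraries.
#' Library 1 is the untreated control; libraries 2..n_libraries are
#' "treated" and carry the spiked fold changes.
#'
#' Defaults emulate a scaled-down DGE experiment: a few thousand genes,
#' 1e5 raw tags per library (the real libraries carry ~4.5-4.9 million raw
#' tags; depth is scaled so the whole pipeline runs in seconds), log-uniform
#' baseline expression spanning three decades, mild negative-binomial
#' overdispersion, and artifact classes mirroring the cleaning filters
#' (adaptor-only reads, N-containing reads, abnormal-length reads, empty
#' reads). Singletons are not injected; they arise naturally from sampling.
#'
#' @param n_genes number of reference transcripts.
#' @param transcript_length_range length range (nt), minimum 25 so at least
#'   one CATG + 17-nt tag fits.
#' @param n_libraries number of libraries (first = control).
#' @param library_depth raw tags per library.
#' @param baseline_mean_log10_range log10 range of baseline expression
#'   weights (relative abundances; only ratios matter).
#' @param dispersion negative-binomial overdispersion phi, with
#'   variance = mu + phi * mu^2; 0 gives Poisson/multinomial sampling.
#' @param de_fraction fraction of genes that are differentially expressed in
#'   treated libraries.
#' @param de_fold_changes pool of fold changes assigned to DE genes.
#' @param error_rate per-base substitution probability in genuine reads.
#' @param artifact_rates named list with elements `adaptor_only`,
#'   `contains_N`, `abnormal_length`, `empty`: per-read injection
#'   probabilities; must sum to < 1.
#' @param taggable_fraction minimum fraction of transcripts guaranteed to
#'   contain an eligible CATG site (a site is implanted when the random
#'   sequence lacks one).
#' @param three_prime_weight probability that a genuine read comes from the
#'   3'-most CATG site of its gene (remaining sites uniform); reflects MmeI
#'   library chemistry.
#' @param n_terms number of annotation terms to simulate.
#' @param genes_per_term_range genes annotated per term.
#' @param seed master seed; per-library child seeds are derived from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000,
                             transcript_length_range = c(300, 3000),
                             n_libraries = 2,
                             library_depth = 100000,
                             baseline_mean_log10_range = c(0, 3),
                             dispersion = 0.1,
                             de_fraction = 0.1,
                             de_fold_changes = c(0.25, 0.5, 2, 4),
                             error_rate = 0.005,
                             artifact_rates = list(adaptor_only = 0.01,
                                                   contains_N = 0.01,
                                                   abnormal_length = 0.005,
                                                   empty = 0.005),
                             taggable_fraction = 0.98,
                             three_prime_weight = 0.8,
                             n_terms = 50,
                             genes_per_term_range = c(10, 100),
                             seed = 1L) {
  stopifnot(n_genes >= 1, n_libraries >= 1, library_depth >= 1,
            length(transcript_length_range) == 2,
            length(baseline_mean_log10_range) == 2,
            dispersion >= 0, de_fraction >= 0, de_fraction <= 1,
            all(de_fold_changes > 0),
            error_rate >= 0, error_rate <= 1,
            taggable_fraction >= 0, taggable_fraction <= 1,
            three_prime_weight >= 0, three_prime_weight <= 1,
            n_terms >= 0, length(genes_per_term_range) == 2)
  if (transcript_length_range[1] < 25) {
    stop("transcript lengths must be >= 25 (room for one CATG + 17 nt)")
  }
  need <- c("adaptor_only", "contains_N", "abnormal_length", "empty")
  if (!all(need %in% names(artifact_rates))) {
    stop("artifact_rates must name: ", paste(need, collapse = ", "))
  }
  rates <- unlist(artifact_rates[need])
  if (any(rates < 0) || any(rates > 1) || sum(rates) >= 1) {
    stop("artifact rates must lie in [0,1] and sum to < 1")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    transcript_length_range = as.integer(transcript_length_range),
    n_libraries = as.integer(n_libraries),
    library_depth = as.integer(library_depth),
    baseline_mean_log10_range = as.numeric(baseline_mean_log10_range),
    dispersion = dispersion,
    de_fraction = de_fraction,
    de_fold_changes = de_fold_changes,
    error_rate = error_rate,
    artifact_rates = as.list(rates),
    taggable_fraction = taggable_fraction,
    three_prime_weight = three_prime_weight,
    n_terms = as.integer(n_terms),
    genes_per_term_range = as.integer(genes_per_term_range),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default adaptor sequences
#'
#' Illumina-style adaptor strings used both by the simulator (adaptor-only
#' artifact reads) and by [clean_tags()] (prefix detection). The exact
#' sequences are arbitrary placeholders for whichever adaptors a real
#' library used; pass your own where it matters.
#'
#' @return character vector of adaptor sequences.
#' @export
dge_default_adaptors <- function() {
  c("AGATCGGAAGAGCGGTTCAG", "AGATCGGAAGAGCGTCGTGT")
}

#' Generate a synthetic reference transcriptome
#'
#' Transcripts are i.i.d. uniform DNA; a CATG anchor with 17 nt of
#' downstream room is implanted where the random sequence happens to lack an
#' eligible site, so that at least `taggable_fraction` of transcripts carry
#' at least one virtual tag site.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `gene_id`, `sequence`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_genes
  lens <- sample(seq(config$transcript_length_range[1],
                     config$transcript_length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  n_force <- ceiling(config$taggable_fraction * n)
  if (n_force > 0) {
    for (i in seq_len(n_force)) {
      if (!has_eligible_site(seqs[i])) {
        L <- lens[i]
        pos <- sample.int(L - 20L, 1L)  # anchor start, 17 nt must follow
        substr(seqs[i], pos, pos + 3L) <- TAG_ANCHOR
      }
    }
  }
  data.frame(gene_id = sprintf("G%05d", seq_len(n)),
             sequence = seqs, stringsAsFactors = FALSE)
}

# does the sequence contain CATG with >= 17 nt downstream?
has_eligible_site <- function(seq) {
  pos <- gregexpr(TAG_ANCHOR, seq, fixed = TRUE)[[1]]
  any(pos > 0 & pos + TAG_LENGTH - 1L <= nchar(seq))
}

# all eligible tag sites of one sequence (sense strand), 3'-most first
tag_sites <- function(seq) {
  pos <- gregexpr(TAG_ANCHOR, seq, fixed = TRUE)[[1]]
  pos <- pos[pos > 0 & pos + TAG_LENGTH - 1L <= nchar(seq)]
  if (length(pos) == 0) {
    return(data.frame(position = integer(0), tag = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  tags <- substring(seq, pos, pos + TAG_LENGTH - 1L)
  keep <- !grepl("N", tags, fixed = TRUE)
  pos <- pos[keep]; tags <- tags[keep]
  ord <- order(pos, decreasing = TRUE)  # rank 0 = 3'-most
  data.frame(position = pos[ord] - 1L,  # 0-based anchor offset
             tag = tags[ord],
             rank = seq_along(pos) - 1L,
             stringsAsFactors = FALSE)
}

#' Generate per-gene expression truth
#'
#' Baseline expression weights are drawn log-uniformly; a
#' `round(de_fraction * n_genes)` subset of genes with at least one virtual
#' tag site is flagged DE and assigned a fold change from
#' `de_fold_changes` (applied in every treated library); all other genes
#' have fold change exactly 1.
#'
#' @param config a [synthetic_config()].
#' @param reference output of [generate_reference()] (or compatible
#'   data.frame / named vector).
#' @return a `ground_truth` list: `genes` data.frame (gene_id,
#'   baseline_mean, fold_change, is_de, n_tag_sites), `de_gene_ids`,
#'   `tags` (list of canonical 21-nt tags per gene), `unmappable_gene_ids`.
#' @export
generate_truth <- function(config, reference) {
  stopifnot(inherits(config, "synthetic_config"))
  seqs <- as_reference_vector(reference)
  if (length(seqs) == 0) stop("reference must be nonempty")
  set.seed(child_seed(config$seed, 2L))
  n <- length(seqs)
  lo <- config$baseline_mean_log10_range[1]
  hi <- config$baseline_mean_log10_range[2]
  baseline <- 10^runif(n, lo, hi)
  sites <- lapply(seqs, tag_sites)
  n_sites <- vapply(sites, nrow, integer(1))
  mappable <- names(seqs)[n_sites > 0]
  n_de <- round(config$de_fraction * n)
  if (n_de > length(mappable)) {
    warning("requested ", n_de, " DE genes but only ", length(mappable),
            " genes have a virtual tag site; assigning DE to those only")
    n_de <- length(mappable)
  }
  de_ids <- if (n_de > 0) sort(sample(mappable, n_de)) else character(0)
  fc <- rep(1, n)
  names(fc) <- names(seqs)
  if (n_de > 0) {
    fc[de_ids] <- sample(config$de_fold_changes, n_de, replace = TRUE)
  }
  genes <- data.frame(gene_id = names(seqs),
                      baseline_mean = baseline,
                      fold_change = unname(fc),
                      is_de = names(seqs) %in% de_ids,
                      n_tag_sites = unname(n_sites),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 de_gene_ids = de_ids,
                 tags = lapply(sites, `[[`, "tag"),
                 sites = sites,
                 unmappable_gene_ids = names(seqs)[n_sites == 0]),
            class = "ground_truth")
}

#' Simulate one library of raw tag reads
#'
#' Each genuine read is one of its gene's virtual tags (CATG + 17 nt), with
#' the 3'-most site favoured (`three_prime_weight`) and i.i.d. per-base
#' substitution errors at `error_rate`. Genes are sampled in proportion to
#' baseline_mean x fold_change (fold change applies in treated libraries
#' only, i.e. `library_id > 1`), with multiplicative gamma noise giving
#' negative-binomial-like per-gene counts at the configured dispersion.
#' Artifact reads (adaptor-only, N-containing, abnormal-length, empty) are
#' injected at `artifact_rates`; genuine + artifact counts always total
#' `library_depth` exactly.
#'
#' @param reference reference transcriptome (see [generate_reference()]).
#' @param truth output of [generate_truth()] on the same reference.
#' @param config the [synthetic_config()].
#' @param library_id integer library index in 1..n_libraries.
#' @return list with `reads` (character, length `library_depth`, shuffled),
#'   `true_counts` (named integer vector: genuine reads that originated from
#'   each gene), `artifact_counts` (named integer vector per class), and
#'   `library_id`.
#' @export
simulate_tag_reads <- function(reference, truth, config, library_id = 1L) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "ground_truth"),
            library_id >= 1, library_id <= config$n_libraries)
  seqs <- as_reference_vector(reference)
  stopifnot(identical(names(seqs), truth$genes$gene_id))
  set.seed(child_seed(config$seed, 100L + as.integer(library_id)))

  depth <- config$library_depth
  rates <- unlist(config$artifact_rates)
  classes <- c(names(rates), "genuine")
  probs <- c(rates, 1 - sum(rates))
  cls <- sample(classes, depth, replace = TRUE, prob = probs)
  n_by_class <- table(factor(cls, levels = classes))
  n_genuine <- as.integer(n_by_class[["genuine"]])

  g <- truth$genes
  treated <- library_id > 1L
  mu <- g$baseline_mean * (if (treated) g$fold_change else 1)
  emissible <- g$n_tag_sites > 0
  lambda <- mu
  if (config$dispersion > 0) {
    shape <- 1 / config$dispersion
    lambda <- rgamma(length(mu), shape = shape, rate = shape / mu)
  }
  lambda[!emissible] <- 0
  if (sum(lambda) <= 0) stop("no mappable gene has positive expression")

  gene_idx <- sample.int(length(lambda), n_genuine, replace = TRUE,
                         prob = lambda)
  true_counts <- tabulate(gene_idx, nbins = length(lambda))
  names(true_counts) <- g$gene_id

  genuine <- emit_reads(gene_idx, truth, config)
  genuine <- apply_substitutions(genuine, config$error_rate)

  reads <- character(depth)
  reads[cls == "genuine"] <- genuine
  reads[cls == "adaptor_only"] <-
    sample(dge_default_adaptors(), n_by_class[["adaptor_only"]],
           replace = TRUE)
  reads[cls == "contains_N"] <- n_reads(n_by_class[["contains_N"]])
  reads[cls == "abnormal_length"] <-
    abnormal_reads(n_by_class[["abnormal_length"]])
  reads[cls == "empty"] <- ""

  structure(list(reads = reads,
                 true_counts = true_counts,
                 artifact_counts = as.integer(n_by_class[names(rates)]),
                 library_id = as.integer(library_id)),
            class = "simulated_library") -> out
  names(out$artifact_counts) <- names(rates)
  out
}

# pick a tag site per genuine read: 3'-most with prob w, rest uniform
emit_reads <- function(gene_idx, truth, config) {
  if (length(gene_idx) == 0) return(character(0))
  w <- config$three_prime_weight
  tags <- truth$tags
  n_sites <- lengths(tags)[gene_idx]
  site <- rep(1L, length(gene_idx))  # tags are stored 3'-most first
  multi <- which(n_sites > 1)
  if (length(multi) > 0) {
    use_top <- runif(length(multi)) < w
    other <- !use_top
    if (any(other)) {
      # uniform over the remaining (n_sites - 1) sites
      site[multi[other]] <- 2L +
        floor(runif(sum(other)) * (n_sites[multi[other]] - 1L))
    }
  }
  mapply(function(gi, si) tags[[gi]][si], gene_idx, site, USE.NAMES = FALSE)
}

# i.i.d. per-base substitutions; vectorized for the common 0/1-error reads
apply_substitutions <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  len <- nchar(reads)
  nerr <- rbinom(length(reads), len, error_rate)
  one <- which(nerr == 1L)
  if (length(one) > 0) {
    pos <- 1L + floor(runif(length(one)) * len[one])
    cur <- substring(reads[one], pos, pos)
    new <- .BASE_ALT[cbind(match(cur, DNA_BASES),
                           sample.int(3L, length(one), replace = TRUE))]
    substr(reads[one], pos, pos) <- new
  }
  multi <- which(nerr > 1L)
  for (i in multi) {
    pos <- sample.int(len[i], nerr[i])
    for (p in pos) {
      cur <- substring(reads[i], p, p)
      substr(reads[i], p, p) <- sample(.BASE_ALT[match(cur, DNA_BASES), ], 1)
    }
  }
  reads
}

# 21-mers carrying at least one N
n_reads <- function(n) {
  if (n == 0) return(character(0))
  out <- vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, TAG_LENGTH, replace = TRUE), collapse = "")
  }, character(1))
  pos <- sample.int(TAG_LENGTH, n, replace = TRUE)
  substr(out, pos, pos) <- "N"
  out
}

# random ACGT reads of length != 21
abnormal_reads <- function(n) {
  if (n == 0) return(character(0))
  lens <- sample(c(10:20, 22:32), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a gene-to-term annotation table
#'
#' Terms are independent flat labels over the four ontology classes used by
#' the enrichment module (CC, MF, BP, PATHWAY); each term annotates a
#' uniform random gene subset.
#'
#' @param config a [synthetic_config()].
#' @param reference the reference transcriptome.
#' @return data.frame with columns `gene_id`, `term_id`, `ontology`.
#' @export
generate_annotation <- function(config, reference) {
  stopifnot(inherits(config, "synthetic_config"))
  seqs <- as_reference_vector(reference)
  set.seed(child_seed(config$seed, 3L))
  if (config$n_terms == 0) {
    return(data.frame(gene_id = character(0), term_id = character(0),
                      ontology = character(0), stringsAsFactors = FALSE))
  }
  onts <- c("CC", "MF", "BP", "PATHWAY")
  lo <- min(config$genes_per_term_range)
  hi <- min(max(config$genes_per_term_range), length(seqs))
  out <- lapply(seq_len(config$n_terms), function(i) {
    k <- sample(seq(lo, hi), 1)
    data.frame(gene_id = sample(names(seqs), k),
               term_id = sprintf("TERM%04d", i),
               ontology = onts[1 + (i - 1) %% length(onts)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write ground truth as TSV
#'
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  g <- truth$genes
  g$tags <- vapply(truth$tags, paste, character(1), collapse = ",")
  write_tsv(g, path)
}
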