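#' Hypergeometric upper-tail probability
#'
#' Probability that at least `m` of `n` drawn genes are annotated to a term,
#' when `M` of the `N` universe genes carry the annotation:
#' \deqn{P = \Pr[X \ge m] = \sum_{i=m}^{\min(n,M)}
#'   \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}}
#' (equivalently \eqn{1 - \sum_{i=0}^{m-1}}), evaluated exactly in log
#' space — no normal approximation.
#'
#' @param m annotated genes among the drawn set.
#' @param n size of the drawn set (e.g. annotated DEGs).
#' @param M genes annotated to the term in the universe.
#' @param N universe size (all annotated genes).
#' @return probability in \[0, 1\]; exactly 1 when `m = 0`.
#' @export
hypergeom_upper_tail <- function(m, n, M, N) {
  stopifnot(m >= 0, n >= 0, M >= 0, N >= 0,
            m == floor(m), n == floor(n), M == floor(M), N == floor(N))
  if (M > N || n > N || m > min(n, M)) {
    stop("arguments must satisfy m <= min(n, M), M <= N, n <= N")
  }
  if (m == 0) return(1)
  i <- m:min(n, M)
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  min(1, sum(exp(lt)))
}

#' Build an annotation table
#'
#' Flat gene-to-term annotations over independent ontology classes; no
#' ontology graph propagation is performed (pre-propagated annotations are
#' accepted as-is).
#'
#' @param df data.frame with columns `gene_id`, `term_id`, `ontology`
#'   (values among CC, MF, BP, PATHWAY) and optionally `term_name`.
#' @return an `annotation_table`: list with the long table plus
#'   `genes_by_term` and `terms_by_gene` inverse maps (consistent by
#'   construction) and `ontology_of` (term -> ontology).
#' @export
annotation_table <- function(df) {
  stopifnot(all(c("gene_id", "term_id", "ontology") %in% names(df)))
  df <- unique(df[, intersect(c("gene_id", "term_id", "ontology",
                                "term_name"), names(df))])
  structure(list(
    table = df,
    genes_by_term = lapply(split(df$gene_id, df$term_id), unique),
    terms_by_gene = lapply(split(df$term_id, df$gene_id), unique),
    ontology_of = vapply(split(df$ontology, df$term_id),
                         function(x) x[1], character(1))
  ), class = "annotation_table")
}

#' Term enrichment of a DEG set
#'
#' One hypergeometric upper-tail test per term with at least one annotated
#' universe gene, performed separately within each ontology: the universe
#' `N` is the set of genes carrying at least one annotation in that
#' ontology (intersected with `universe` when given), `n` the annotated
#' DEGs, `M` and `m` the term's universe genes and DEGs. Multiplicity
#' correction (`Q`) is applied over the tested terms of each ontology;
#' `significant` means `Q <= alpha`.
#'
#' @param deg_genes character vector of DEG gene ids.
#' @param annotation an [annotation_table()] (or a compatible data.frame).
#' @param universe optional restriction of the gene universe; by default
#'   all annotated genes of the ontology.
#' @param alpha significance threshold on the corrected value.
#' @param correction `"BH"` or `"bonferroni"`.
#' @return data.frame of enrichment records sorted by `Q` within ontology:
#'   `term_id`, `ontology`, `N`, `n`, `M`, `m`, `P`, `Q`, `significant`;
#'   attribute `deg_genes` keeps the tested DEG set.
#' @export
enrich <- function(deg_genes, annotation, universe = NULL, alpha = 0.05,
                   correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  if (is.data.frame(annotation)) annotation <- annotation_table(annotation)
  stopifnot(inherits(annotation, "annotation_table"))
  df <- annotation$table
  deg_genes <- unique(deg_genes)

  out <- lapply(split(df, df$ontology), function(sub) {
    uni <- unique(sub$gene_id)
    if (!is.null(universe)) uni <- intersect(uni, universe)
    if (length(uni) == 0) stop("empty annotated universe")
    degs <- intersect(deg_genes, uni)
    if (length(degs) == 0) {
      warning("DEG set disjoint from the annotated universe (",
              sub$ontology[1], "); all P = 1")
    }
    N <- length(uni)
    n <- length(degs)
    terms <- unique(sub$term_id)
    rec <- lapply(terms, function(t) {
      tg <- intersect(annotation$genes_by_term[[t]], uni)
      M <- length(tg)
      if (M == 0) return(NULL)
      m <- length(intersect(tg, degs))
      data.frame(term_id = t, ontology = sub$ontology[1],
                 N = N, n = n, M = M, m = m,
                 P = hypergeom_upper_tail(m, n, M, N),
                 stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rec)
    if (is.null(rec)) return(NULL)
    rec$Q <- if (correction == "BH") bh_fdr(rec$P) else
      pmin(1, rec$P * nrow(rec))
    rec$significant <- rec$Q <= alpha
    rec[order(rec$Q, rec$P, rec$term_id), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, deg_genes = deg_genes, alpha = alpha,
            correction = correction)
}

#' Per-ontology histogram of significant terms
#'
#' For each ontology: the number of significant terms ("functional groups")
#' and the number of distinct DEGs annotated to at least one of them (a
#' gene in several significant terms is counted once).
#'
#' @param records an [enrich()] result.
#' @param annotation the [annotation_table()] used for the enrichment.
#' @return data.frame with columns `ontology`, `n_significant_terms`,
#'   `n_genes`.
#' @export
ontology_histogram <- function(records, annotation) {
  if (is.data.frame(annotation) && !inherits(annotation, "annotation_table")) {
    annotation <- annotation_table(annotation)
  }
  deg_genes <- attr(records, "deg_genes")
  onts <- sort(unique(records$ontology))
  out <- lapply(onts, function(o) {
    sig <- records$term_id[records$ontology == o & records$significant]
    genes <- unique(unlist(annotation$genes_by_term[sig], use.names = FALSE))
    data.frame(ontology = o,
               n_significant_terms = length(sig),
               n_genes = length(intersect(genes, deg_genes)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
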