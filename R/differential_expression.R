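#' Audic-Claverie conditional probability
#'
#' Probability of observing `y` copies of a tag in a library of size `N2`
#' given `x` copies in a library of size `N1`, under the exact test for
#' tag-count data:
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' evaluated in log space. Summed over all `y` this is a proper
#' distribution (it is a negative binomial in `y` with size `x+1` and
#' success probability `N1/(N1+N2)`, a fact the test-suite uses as an
#' independent check).
#'
#' @param y,x non-negative integer counts (`y` may be a vector).
#' @param n1,n2 positive library totals (clean tags).
#' @param log return the log probability.
#' @return numeric vector of probabilities (or log probabilities).
#' @export
ac_probability <- function(y, x, n1, n2, log = FALSE) {
  stopifnot(length(x) == 1, all(y >= 0), x >= 0, n1 > 0, n2 > 0,
            x == floor(x), all(y == floor(y)))
  r <- n2 / n1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) -
    lgamma(y + 1) - (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

# log of sum(exp(lp)) without overflow
logsumexp <- function(lp) {
  m <- max(lp)
  if (!is.finite(m)) return(m)
  m + base::log(sum(exp(lp - m)))
}

# log P(Y <= y | x): exact finite sum
ac_lower_tail_log <- function(x, y, n1, n2) {
  logsumexp(ac_probability(0:y, x, n1, n2, log = TRUE))
}

# log P(Y >= y | x): sum upward until the tail is negligible
ac_upper_tail_log <- function(x, y, n1, n2) {
  r <- n2 / n1
  mode_y <- max(x * r, y)
  hi <- ceiling(mode_y + 12 * sqrt(mode_y + 10) + 50)
  repeat {
    lp <- ac_probability(y:hi, x, n1, n2, log = TRUE)
    # terms decay geometrically beyond the mode; stop once the last term
    # cannot move the sum at double precision
    if (lp[length(lp)] < max(lp) - 40 || lp[length(lp)] == -Inf) break
    hi <- hi * 2 + 100
  }
  logsumexp(lp)
}

#' Audic-Claverie two-sided p-value
#'
#' Doubles the smaller of the two tail probabilities of `y` under
#' `ac_probability`, capped at 1 (the `"doubled_tail"` method). The
#' `"minlike"` alternative sums the probabilities of all outcomes at most
#' as likely as the observed `y`.
#'
#' @param x,y non-negative integer counts in libraries 1 and 2.
#' @param n1,n2 positive library totals.
#' @param method `"doubled_tail"` (default) or `"minlike"`.
#' @return p-value in (0, 1].
#' @export
ac_two_sided_p <- function(x, y, n1, n2,
                           method = c("doubled_tail", "minlike")) {
  method <- match.arg(method)
  stopifnot(x >= 0, y >= 0, n1 > 0, n2 > 0)
  if (method == "doubled_tail") {
    lo <- exp(ac_lower_tail_log(x, y, n1, n2))
    up <- exp(ac_upper_tail_log(x, y, n1, n2))
    min(1, 2 * min(lo, up))
  } else {
    p_obs <- ac_probability(y, x, n1, n2, log = TRUE)
    r <- n2 / n1
    mode_y <- max(x * r, y)
    hi <- ceiling(mode_y + 12 * sqrt(mode_y + 10) + 50)
    lp <- ac_probability(0:hi, x, n1, n2, log = TRUE)
    while (lp[length(lp)] > max(lp) - 40 && is.finite(lp[length(lp)])) {
      hi <- hi * 2 + 100
      lp <- ac_probability(0:hi, x, n1, n2, log = TRUE)
    }
    min(1, sum(exp(lp[lp <= p_obs + 1e-12])))
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q(i) = min over j >= i of m p(j)/j on the sorted
#' p-values, mapped back to input order. A validated front door over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values, elementwise >= the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' For each gene present in either library the Audic-Claverie two-sided
#' p-value is computed on the raw unambiguous counts, adjusted by
#' Benjamini-Hochberg over all tested genes, and the gene is flagged `up`
#' (`fdr <= fdr_threshold` and `log2_ratio >= log2_threshold`) or `down`
#' (`fdr <= fdr_threshold` and `log2_ratio <= -log2_threshold`). The ratio
#' is `log2(tpm2/tpm1)`; when exactly one side is zero that side is floored
#' at `pseudo_tpm` so the ratio stays finite while nonzero genes stay
#' exact. Genes with zero counts in both libraries are excluded before the
#' FDR correction.
#'
#' @param expr1,expr2 [quantify()] results over the same gene universe
#'   (library 1 is the control/reference).
#' @param fdr_threshold,log2_threshold significance thresholds (the
#'   conventional rigorous cutoffs are 0.001 and 1).
#' @param pseudo_tpm TPM floor for zero counts in the ratio.
#' @param method p-value sidedness, see [ac_two_sided_p()].
#' @return data.frame of DEG records: `gene_id`, `x`, `y`, `tpm1`, `tpm2`,
#'   `log2_ratio`, `p_value`, `fdr`, `status`; attributes `N1`, `N2`,
#'   `n_excluded` (genes with x = y = 0).
#' @export
call_degs <- function(expr1, expr2, fdr_threshold = 0.001,
                      log2_threshold = 1, pseudo_tpm = 0.001,
                      method = "doubled_tail") {
  stopifnot(inherits(expr1, "gene_expression_table"),
            inherits(expr2, "gene_expression_table"))
  if (!identical(expr1$gene_id, expr2$gene_id)) {
    stop("expression tables must share one gene universe")
  }
  n1 <- attr(expr1, "library_clean_total")
  n2 <- attr(expr2, "library_clean_total")
  keep <- expr1$raw_count > 0 | expr2$raw_count > 0
  x <- expr1$raw_count[keep]
  y <- expr2$raw_count[keep]
  tpm1 <- expr1$tpm[keep]
  tpm2 <- expr2$tpm[keep]

  p <- vapply(seq_along(x), function(i) {
    ac_two_sided_p(x[i], y[i], n1, n2, method = method)
  }, numeric(1))
  fdr <- bh_fdr(p)
  l2r <- log2(pmax(tpm2, ifelse(tpm2 == 0, pseudo_tpm, 0)) /
                pmax(tpm1, ifelse(tpm1 == 0, pseudo_tpm, 0)))
  status <- rep("not_significant", length(x))
  status[fdr <= fdr_threshold & l2r >= log2_threshold] <- "up"
  status[fdr <= fdr_threshold & l2r <= -log2_threshold] <- "down"

  out <- data.frame(gene_id = expr1$gene_id[keep],
                    x = x, y = y, tpm1 = tpm1, tpm2 = tpm2,
                    log2_ratio = l2r, p_value = p, fdr = fdr,
                    status = status, stringsAsFactors = FALSE)
  structure(out, class = c("deg_table", "data.frame"),
            N1 = n1, N2 = n2, n_excluded = sum(!keep),
            fdr_threshold = fdr_threshold, log2_threshold = log2_threshold)
}

#' Fold-change distribution of tested genes
#'
#' Bins fold changes (2^log2_ratio) into |FC| < boundary, FC >= boundary
#' (up) and FC <= 1/boundary (down), with the boundary inclusive on the
#' extreme bins; percentages are over all tested items and sum to 100.
#'
#' @param records a [call_degs()] table (or any data.frame with a
#'   `log2_ratio` column).
#' @param boundary fold-change boundary, > 1 (the conventional display
#'   uses 5).
#' @return data.frame with columns `bin`, `count`, `pct`.
#' @export
fold_change_distribution <- function(records, boundary = 5) {
  if (boundary <= 1) stop("boundary must be > 1")
  fc <- 2^records$log2_ratio
  up <- fc >= boundary
  down <- fc <= 1 / boundary
  mid <- !up & !down
  counts <- c(sum(mid), sum(up), sum(down))
  data.frame(
    bin = c(sprintf("<%g-fold", boundary),
            sprintf(">=%g-fold up", boundary),
            sprintf(">=%g-fold down", boundary)),
    count = counts,
    pct = if (length(fc) > 0) 100 * counts / length(fc) else rep(0, 3),
    stringsAsFactors = FALSE)
}

#' Summarize a DEG comparison
#'
#' @param records a [call_degs()] table.
#' @param boundary fold-change boundary for [fold_change_distribution()].
#' @return a `comparison_summary` list: `n_up`, `n_down`, `n_deg`
#'   (= n_up + n_down), `n_tested`, `fold_change_bins`.
#' @export
comparison_summary <- function(records, boundary = 5) {
  n_up <- sum(records$status == "up")
  n_down <- sum(records$status == "down")
  structure(list(n_up = n_up, n_down = n_down,
                 n_deg = n_up + n_down,
                 n_tested = nrow(records),
                 fold_change_bins = fold_change_distribution(records,
                                                             boundary)),
            class = "comparison_summary")
}

#' Overlap between two DEG sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list with `a_only`, `b_only`, `overlap` counts and the shared
#'   ids in `overlap_genes`.
#' @export
compare_deg_sets <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  list(a_only = length(setdiff(set_a, set_b)),
       b_only = length(setdiff(set_b, set_a)),
       overlap = length(shared),
       overlap_genes = sort(shared))
}

#' Volcano-plot-ready table
#'
#' log10 TPMs of the two libraries (with the same pseudo floor as the
#' ratio) plus status, matching the usual DGE scatter axes.
#'
#' @param records a [call_degs()] table.
#' @param pseudo_tpm floor for zero TPMs on the log scale.
#' @return data.frame with `gene_id`, `log10_tpm1`, `log10_tpm2`,
#'   `log2_ratio`, `fdr`, `status`.
#' @export
volcano_table <- function(records, pseudo_tpm = 0.001) {
  data.frame(gene_id = records$gene_id,
             log10_tpm1 = log10(pmax(records$tpm1, pseudo_tpm)),
             log10_tpm2 = log10(pmax(records$tpm2, pseudo_tpm)),
             log2_ratio = records$log2_ratio,
             fdr = records$fdr,
             status = records$status,
             stringsAsFactors = FALSE)
}
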