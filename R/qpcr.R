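#' Relative expression by the 2^-ddCt method
#'
#' Computes \eqn{2^{-\Delta\Delta Ct}} with
#' \eqn{\Delta\Delta Ct = (Ct_{target} - Ct_{reference})_{treated} -
#' (Ct_{target} - Ct_{reference})_{control}}: the treated sample's
#' expression relative to the control, each normalized to an internal
#' reference gene (e.g. 18S rRNA). The control compared against itself is
#' exactly 1.
#'
#' @param treated,control lists or one-row data.frames with fields
#'   `gene_id`, `ct_target`, `ct_reference` (cycle-threshold values;
#'   replicate Ct values should be averaged beforehand, see
#'   [qpcr_relative_table()]).
#' @return the relative expression level (positive real).
#' @export
relative_level <- function(treated, control) {
  check_ct <- function(r, what) {
    if (is.null(r$gene_id) || is.null(r$ct_target) || is.null(r$ct_reference))
      stop(what, " must carry gene_id, ct_target, ct_reference")
    if (!all(is.finite(c(r$ct_target, r$ct_reference))) ||
        any(c(r$ct_target, r$ct_reference) <= 0))
      stop("Ct values must be positive and finite")
  }
  check_ct(treated, "treated")
  check_ct(control, "control")
  if (!identical(treated$gene_id, control$gene_id)) {
    stop("treated and control records refer to different genes")
  }
  ddct <- (treated$ct_target - treated$ct_reference) -
    (control$ct_target - control$ct_reference)
  2^(-ddct)
}

#' Relative expression table from raw Ct measurements
#'
#' Averages replicate Ct values per (sample, gene), then computes the
#' 2^-ddCt level of every non-control sample relative to `control_sample`
#' for each gene; the control itself is reported as exactly 1.
#'
#' @param ct data.frame with columns `sample_id`, `gene_id`, `ct_target`,
#'   `ct_reference` (one row per replicate measurement).
#' @param control_sample the sample id serving as calibrator.
#' @return data.frame with columns `sample_id`, `gene_id`,
#'   `relative_level`.
#' @export
qpcr_relative_table <- function(ct, control_sample) {
  stopifnot(all(c("sample_id", "gene_id", "ct_target", "ct_reference")
                %in% names(ct)))
  if (!control_sample %in% ct$sample_id) {
    stop("control sample ", control_sample, " not present")
  }
  agg <- aggregate(cbind(ct_target, ct_reference) ~ sample_id + gene_id,
                   data = ct, FUN = mean)
  out <- lapply(seq_len(nrow(agg)), function(i) {
    row <- agg[i, ]
    ctrl <- agg[agg$sample_id == control_sample &
                  agg$gene_id == row$gene_id, ]
    if (nrow(ctrl) != 1) {
      stop("gene ", row$gene_id, " has no control measurement")
    }
    data.frame(sample_id = row$sample_id, gene_id = row$gene_id,
               relative_level = relative_level(row, ctrl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Concordance between DGE fold changes and qPCR levels
#'
#' Compares per-gene DGE `log2` ratios with qPCR relative levels over the
#' shared genes: the fraction of genes on which the signs of the DGE
#' log2-ratio and of log2(qPCR level) agree, and the Spearman rank
#' correlation of the two vectors.
#'
#' @param dge_log2fc named numeric vector of DGE log2 ratios.
#' @param qpcr_levels named numeric vector of qPCR relative levels
#'   (positive).
#' @return list with `n_genes`, `sign_agreement`, `rank_correlation`.
#' @export
concordance <- function(dge_log2fc, qpcr_levels) {
  shared <- intersect(names(dge_log2fc), names(qpcr_levels))
  if (length(shared) < 2) stop("need at least 2 shared genes")
  a <- dge_log2fc[shared]
  b <- log2(qpcr_levels[shared])
  list(n_genes = length(shared),
       sign_agreement = mean(sign(a) == sign(b)),
       rank_correlation = cor(a, b, method = "spearman"))
}
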