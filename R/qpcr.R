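# qPCR relative quantification (2^-ddCt against an internal reference
# gene such as Actin) and concordance of paired platform vs qPCR log2
# ratios.

#' Relative expression by the 2^-ddCt method
#'
#' Per tissue, `dCt = mean(ct_target) - mean(ct_reference)` over
#' replicates; `ddCt = dCt_A - dCt_B`; the returned value is the log2
#' fold change `-ddCt`, so that fold = `2^-ddCt`. One extra cycle in
#' tissue B relative to A corresponds to a log2 fold of +1.
#'
#' @param ct data.frame with columns `gene_id`, `tissue`, `replicate`,
#'   `ct_target`, `ct_reference` for ONE gene (Ct values in (0, 45)).
#' @param tissue_a,tissue_b the contrast (log2 fold of A over B).
#' @return log2 fold change (scalar).
#' @export
delta_delta_ct <- function(ct, tissue_a, tissue_b) {
  stopifnot(all(c("gene_id", "tissue", "ct_target", "ct_reference")
                %in% names(ct)))
  if (length(unique(ct$gene_id)) != 1L) {
    stop("delta_delta_ct expects records of a single gene")
  }
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45 |
          ct$ct_reference <= 0 | ct$ct_reference >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  dct <- function(tis) {
    sub <- ct[ct$tissue == tis, , drop = FALSE]
    if (!nrow(sub)) stop("missing tissue: ", tis)
    mean(sub$ct_target) - mean(sub$ct_reference)
  }
  -(dct(tissue_a) - dct(tissue_b))
}

#' 2^-ddCt log2 folds for every gene in a Ct table
#'
#' @param ct Ct data.frame (several genes).
#' @inheritParams delta_delta_ct
#' @return data.frame with `gene_id` and `qpcr_log2`.
#' @export
ddct_table <- function(ct, tissue_a, tissue_b) {
  genes <- unique(ct$gene_id)
  data.frame(gene_id = genes,
             qpcr_log2 = vapply(genes, function(g) {
               delta_delta_ct(ct[ct$gene_id == g, , drop = FALSE],
                              tissue_a, tissue_b)
             }, numeric(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Concordance of paired array and qPCR log2 ratios
#'
#' Pearson correlation of the two log2 columns with the usual t-transform
#' p-value on n - 2 degrees of freedom.
#'
#' @param pairs data.frame with columns `array_log2` and `qpcr_log2`
#'   (both finite), at least 3 rows.
#' @return list with `r`, `p`, `n`.
#' @export
concordance <- function(pairs) {
  stopifnot(all(c("array_log2", "qpcr_log2") %in% names(pairs)))
  x <- pairs$array_log2; y <- pairs$qpcr_log2
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite value")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a column")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bundled platform validation pairs
#'
#' The packaged validation set of 66 rice genes assayed for the shoot vs
#' root contrast by both the 60-mer one-channel array and qRT-PCR
#' (2^-ddCt, Actin reference), as paired log2 ratios.
#'
#' @return data.frame with `gene_id`, `array_log2`, `qpcr_log2`.
#' @export
qpcr_validation_pairs <- function() {
  path <- system.file("extdata", "qpcr_validation_pairs.tsv",
                      package = "duoprobe", mustWork = TRUE)
  read_tsv_plain(path)
}
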