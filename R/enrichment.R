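# Term enrichment over gene clusters: one-sided Fisher exact p-values and
# count/percentage reporting. A standard Fisher exact test is used (not
# the hosted EASE-score variant some annotation services apply), so
# p-values from such services are comparable only in rank, while the
# count and percentage columns are exactly reproducible arithmetic.

#' Build an annotation map
#'
#' @param gene_id,term parallel character vectors (one row per
#'   gene-to-term assignment), e.g. the two columns of an annotation TSV.
#' @param background character vector of all assayable gene ids; defaults
#'   to the annotated genes. Every annotated gene must be in the
#'   background.
#' @return list of class `annotation_map` with `term_genes` (term -> gene
#'   set) and `background`.
#' @export
annotation_map <- function(gene_id, term, background = unique(gene_id)) {
  stopifnot(length(gene_id) == length(term))
  extra <- setdiff(unique(gene_id), background)
  if (length(extra)) {
    stop("annotated gene(s) missing from background: ",
         paste(utils::head(extra, 3), collapse = ", "))
  }
  structure(list(term_genes = lapply(split(gene_id, term), unique),
                 background = unique(background)),
            class = "annotation_map")
}

#' One-sided Fisher exact p-value for a 2x2 table
#'
#' Hypergeometric upper tail `P(X >= a)` given the table margins, i.e. the
#' probability of drawing at least `a` annotated genes when sampling the
#' cluster from the background.
#'
#' @param a in-cluster and annotated; @param b in-cluster, not annotated;
#' @param c_ out-of-cluster and annotated; @param d neither.
#' @return p-value in (0, 1].
#' @export
fisher_one_sided <- function(a, b, c_, d) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  # white balls = annotated (a + c_), draws = cluster size (a + b)
  stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}

#' Term enrichment of a gene cluster
#'
#' One row per term with at least one cluster member: gene count,
#' percentage of the cluster (half-up rounded to 2 decimals, matching how
#' such tables are conventionally printed), and one-sided Fisher exact
#' p-value against the background. Rows are sorted by ascending p.
#'
#' @param cluster character vector of gene ids (must be a subset of the
#'   background).
#' @param ann [annotation_map()].
#' @param adjust `"none"` (default) or `"BH"` to append an adjusted-p
#'   column.
#' @return data.frame with `term`, `count`, `cluster_size`, `percentage`,
#'   `p_value` (and `p_adjusted` when requested).
#' @export
enrich <- function(cluster, ann, adjust = "none") {
  adjust <- match.arg(adjust, c("none", "BH"))
  cluster <- unique(cluster)
  if (!length(cluster)) stop("empty cluster")
  extra <- setdiff(cluster, ann$background)
  if (length(extra)) {
    stop("cluster gene(s) not in background: ",
         paste(utils::head(extra, 3), collapse = ", "))
  }
  n_bg <- length(ann$background)
  n_cl <- length(cluster)
  rows <- lapply(names(ann$term_genes), function(tm) {
    genes <- ann$term_genes[[tm]]
    a <- length(intersect(genes, cluster))
    if (a == 0L) return(NULL)
    k <- length(genes)
    data.frame(term = tm, count = a, cluster_size = n_cl,
               percentage = round_half_up(100 * a / n_cl, 2),
               p_value = fisher_one_sided(a, n_cl - a, k - a,
                                          n_bg - n_cl - (k - a)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), count = integer(),
                      cluster_size = integer(), percentage = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  }
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out[order(out$p_value, out$term), , drop = FALSE]
}
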