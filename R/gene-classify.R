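#' Partition genes by strict containment in an interval
#'
#' A gene is inside the interval iff its whole body is contained
#' (`start >= interval[1]` and `end <= interval[2]`); genes straddling a
#' boundary are outside. The partition is exhaustive and disjoint.
#'
#' @param genes Gene table (as from [read_gene_table()]), 1-based inclusive
#'   coordinates on the same contig as the interval.
#' @param interval Length-2 vector `(start, end)`.
#' @return List with data.frames `inside` and `outside`.
#' @export
genes_in_interval <- function(genes, interval) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  inside <- genes$start >= interval[1] & genes$end <= interval[2]
  list(inside = genes[inside, , drop = FALSE],
       outside = genes[!inside, , drop = FALSE])
}

#' Classify differential-expression responses
#'
#' Labels each gene from a supplied DE table (this does not re-fit or
#' re-adjust anything): `over` iff `log2_de > 0` and `fdr_p < alpha`;
#' `under` iff `log2_de < 0` and `fdr_p < alpha`; otherwise
#' `not_significant`. A strict sign rule applies (log2 fold change of
#' exactly 0 is never significant) and the inequality on alpha is strict.
#' Genes with a missing p-value are labeled `not_evaluable` and excluded
#' from the counts.
#'
#' @param de_table data.frame with columns `gene` (or `gene_id`), `log2_de`,
#'   `fdr_p` (already FDR-adjusted p-values).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return List with `labels` (data.frame `gene`, `label`) and `counts`
#'   (named vector `over`, `under`, `not_significant`).
#' @export
classify_expression_response <- function(de_table, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  gene <- if ("gene" %in% names(de_table)) de_table$gene else de_table$gene_id
  if (nrow(de_table) == 0) {
    return(list(labels = data.frame(gene = character(), label = character(),
                                    stringsAsFactors = FALSE),
                counts = c(over = 0L, under = 0L, not_significant = 0L)))
  }
  lfc <- de_table$log2_de
  p <- de_table$fdr_p
  label <- ifelse(is.na(p), "not_evaluable",
           ifelse(p < alpha & lfc > 0, "over",
           ifelse(p < alpha & lfc < 0, "under", "not_significant")))
  counts <- c(over = sum(label == "over"),
              under = sum(label == "under"),
              not_significant = sum(label == "not_significant"))
  list(labels = data.frame(gene = gene, label = label,
                           stringsAsFactors = FALSE),
       counts = counts)
}
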