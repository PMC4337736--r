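# Per-dataset fold-change statistics and the rank list that feeds GWRS.
#
# The integration statistic only consumes the fold-change rank, so the
# per-gene fit is a plain difference of group means on log2 data. A Welch
# t-test plus Benjamini-Hochberg adjustment supplies the conventional
# p < 0.05 & FDR < 0.05 DEG filter, which is reported per gene and can
# optionally be applied before ranking.

#' Per-gene differential-expression table
#'
#' log2 fold change is mean(case) - mean(control) per gene; significance is
#' a two-sided Welch (unequal-variance) t-test with BH adjustment across
#' all genes of the dataset. A gene with zero variance in both groups and
#' equal means gets p = 1; zero variance with unequal means gets p = 0.
#'
#' @param dataset an \code{\link{expression_dataset}}
#' @return data.frame of class \code{de_table} with columns \code{gene},
#'   \code{log2_fc}, \code{p_value}, \code{fdr},
#'   \code{passes_deg_filter} (p < 0.05 and FDR < 0.05); attribute
#'   \code{dataset_id}.
#' @export
compute_de_table <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  case <- dataset$values[, dataset$group == "case", drop = FALSE]
  ctrl <- dataset$values[, dataset$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) stopf("need at least 2 samples per group")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  fc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 > 0, fc / sqrt(se2), ifelse(fc == 0, 0, Inf))
  # Welch-Satterthwaite degrees of freedom; df for the degenerate
  # zero-variance case is irrelevant (|t| is 0 or Inf there)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(dataset$values),
                    log2_fc = unname(fc), p_value = unname(p),
                    fdr = unname(fdr),
                    passes_deg_filter = unname(p < 0.05 & fdr < 0.05),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("de_table", "data.frame"),
            dataset_id = dataset$dataset_id)
}

#' Rank genes by absolute log2 fold change
#'
#' Rank 1 is the most differentially expressed gene (largest |log2 fold
#' change|); ranks run 1..m in descending order of |log2_fc|. Ties are
#' broken by the lexicographically smaller gene id taking the better rank,
#' so the ranking is deterministic and invariant to input row order.
#'
#' @param table a \code{\link{compute_de_table}} result.
#' @param restrict_to optional character vector: rank only these genes
#'   (must all be present in \code{table}); used to rank over the
#'   common-gene intersection.
#' @return data.frame of class \code{ranked_gene_list} with columns
#'   \code{gene}, \code{log2_fc}, \code{rank}; attributes
#'   \code{dataset_id} and \code{m}.
#' @export
rank_by_fold_change <- function(table, restrict_to = NULL) {
  stopifnot(is.data.frame(table), all(c("gene", "log2_fc") %in% colnames(table)))
  df <- table
  if (!is.null(restrict_to)) {
    restrict_to <- unique(as.character(restrict_to))
    if (length(restrict_to) == 0L) stopf("restrict_to is empty")
    absent <- setdiff(restrict_to, df$gene)
    if (length(absent) > 0L)
      stopf("restrict_to contains %d genes absent from the table (first: '%s')",
            length(absent), absent[1L])
    df <- df[df$gene %in% restrict_to, , drop = FALSE]
  }
  if (nrow(df) == 0L) stopf("no genes to rank")
  ord <- order(-abs(df$log2_fc), df$gene)
  out <- data.frame(gene = df$gene[ord], log2_fc = df$log2_fc[ord],
                    rank = seq_len(nrow(df)), stringsAsFactors = FALSE)
  structure(out, class = c("ranked_gene_list", "data.frame"),
            dataset_id = attr(table, "dataset_id"), m = nrow(out))
}

#' Write a DE table (with ranks) as TSV
#'
#' @param table \code{de_table}
#' @param path output path
#' @param ranked optional \code{ranked_gene_list} supplying a \code{rank}
#'   column (genes absent from it get NA).
#' @return invisibly, the path
#' @export
write_de_table <- function(table, path, ranked = NULL) {
  df <- as.data.frame(table)
  if (!is.null(ranked))
    df$rank <- ranked$rank[match(df$gene, ranked$gene)]
  write_tsv_full(df, path)
}
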