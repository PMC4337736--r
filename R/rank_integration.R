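# The core integration statistic.
#
# For m common genes and n studies, a gene's genome-wide relative
# significance (GWRS) in study j is s_ij = -2 * ln(r_ij / m), where r_ij is
# its fold-change rank (1 = most differentially expressed). The genome-wide
# global significance (GWGS) is the weighted sum s_i = sum_j w_j * s_ij with
# weights normalised to 1 (equal by default). With unit weights this is
# exactly Fisher's method applied to the p-like quantities r_ij / m. The
# top-K genes by GWGS (K = 200 by default) form the cross-study signature.

#' Intersect gene universes across studies
#'
#' @param lists a list of >= 2 character vectors of gene ids.
#' @return the common genes in lexicographic order.
#' @export
intersect_genes <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stopf("need at least 2 gene universes to intersect")
  common <- Reduce(intersect, lapply(lists, as.character))
  if (length(common) == 0L)
    stopf("gene universes have an empty intersection: the pipeline cannot proceed")
  sort(common)
}

#' Genome-wide relative significance of a rank
#'
#' \code{-2 * ln(r / m)}: 0 at r = m, maximal (\code{2 ln m}) at r = 1,
#' strictly decreasing in r. Vectorised over \code{r}.
#'
#' @param r integer rank(s) in 1..m.
#' @param m number of ranked (common) genes, >= 1.
#' @return numeric score(s) >= 0.
#' @export
gwrs_score <- function(r, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) stopf("m must be a single integer >= 1")
  if (!is.numeric(r) || any(r < 1 | r > m)) stopf("ranks must lie in 1..m")
  -2 * log(r / m)
}

#' GWRS matrix from per-dataset rank lists
#'
#' @param ranked_lists list of \code{\link{rank_by_fold_change}} results,
#'   all over the same gene universe (the m common genes).
#' @return m x n numeric matrix of GWRS scores, rows = genes
#'   (lexicographic), columns = dataset ids.
#' @export
gwrs_matrix <- function(ranked_lists) {
  if (length(ranked_lists) < 1L) stopf("need at least one ranked list")
  genes <- sort(ranked_lists[[1L]]$gene)
  ids <- vapply(seq_along(ranked_lists), function(j) {
    id <- attr(ranked_lists[[j]], "dataset_id")
    if (is.null(id)) sprintf("dataset%d", j) else id
  }, character(1))
  m <- length(genes)
  mat <- matrix(NA_real_, nrow = m, ncol = length(ranked_lists),
                dimnames = list(genes, ids))
  for (j in seq_along(ranked_lists)) {
    rl <- ranked_lists[[j]]
    if (!setequal(rl$gene, genes))
      stopf("ranked list %d ('%s') covers a different gene universe", j, ids[j])
    mat[, j] <- gwrs_score(rl$rank[match(genes, rl$gene)], m)
  }
  mat
}

#' GWGS: weighted combination of GWRS scores across studies
#'
#' Weights are normalised to sum to 1 before use (equal weights by
#' default), so GWGS values are comparable across different numbers of
#' studies. Global rank 1 is the largest GWGS; ties are broken by the
#' lexicographically smaller gene id.
#'
#' @param gwrs m x n GWRS matrix from \code{\link{gwrs_matrix}}.
#' @param weights per-dataset raw weights (length n, all >= 0, not all 0);
#'   default equal.
#' @return data.frame of class \code{gwgs_table}: \code{gene}, one GWRS
#'   column per dataset, \code{gwgs}, \code{global_rank}; sorted by
#'   \code{global_rank}. Attribute \code{weights} holds the normalised
#'   weights.
#' @export
gwgs_scores <- function(gwrs, weights = NULL) {
  stopifnot(is.matrix(gwrs), is.numeric(gwrs))
  n <- ncol(gwrs)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stopf("weights has length %d but there are %d datasets", length(weights), n)
  if (any(!is.finite(weights)) || any(weights < 0))
    stopf("weights must be finite and >= 0")
  if (sum(weights) == 0) stopf("weights must not all be zero")
  w <- weights / sum(weights)
  s <- as.numeric(gwrs %*% w)
  genes <- rownames(gwrs)
  ord <- order(-s, genes)
  out <- data.frame(gene = genes, gwrs = unname(gwrs),
                    gwgs = s, stringsAsFactors = FALSE)
  colnames(out) <- c("gene", paste0("gwrs_", colnames(gwrs)), "gwgs")
  out <- out[ord, , drop = FALSE]
  out$global_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("gwgs_table", "data.frame"), weights = w)
}

#' Select the top-K signature from a GWGS table
#'
#' @param table a \code{\link{gwgs_scores}} result.
#' @param k signature size (default 200, the smallest size reported to
#'   reach adequate classification performance). If k >= m, all genes are
#'   returned.
#' @return data.frame of class \code{signature}: \code{gene}, \code{gwgs},
#'   \code{global_rank} in GWGS-descending order.
#' @export
select_top_k <- function(table, k = 200L) {
  stopifnot(inherits(table, "gwgs_table"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) stopf("k must be >= 1")
  k <- min(as.integer(k), nrow(table))
  out <- table[seq_len(k), c("gene", "gwgs", "global_rank"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("signature", "data.frame"))
}

#' Write the GWGS table / signature as TSV
#' @param table \code{gwgs_table} or \code{signature}
#' @param path output path
#' @return invisibly, the path
#' @export
write_gwgs_table <- function(table, path) write_tsv_full(as.data.frame(table), path)

#' Write a signature as a one-column gene list
#' @param signature a \code{signature}
#' @param path output path
#' @return invisibly, the path
#' @export
write_gene_list <- function(signature, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("gene", signature$gene), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
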