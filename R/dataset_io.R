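# Expression-dataset container and tabular IO.
#
# One study is a log2 gene-by-sample matrix with case/control labels and a
# dataset weight w_j used later when GWRS scores are combined into GWGS.

#' Construct an expression dataset
#'
#' @param dataset_id single character label for the study.
#' @param values numeric matrix of log2 expression, genes in rows (unique
#'   rownames), samples in columns (unique colnames). All values must be
#'   finite; missing values are rejected because no downstream statistic
#'   defines their handling.
#' @param group character/factor of length \code{ncol(values)} with levels
#'   \code{"case"} and \code{"control"}; each group needs at least 2 samples.
#' @param weight non-negative relative weight of the dataset (default 1).
#' @return an object of class \code{expression_dataset}: a list with fields
#'   \code{dataset_id}, \code{values}, \code{group}, \code{weight}.
#' @export
expression_dataset <- function(dataset_id, values, group, weight = 1) {
  if (!is.character(dataset_id) || length(dataset_id) != 1L || !nzchar(dataset_id))
    stopf("dataset_id must be a non-empty string")
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene ids in dataset '%s'; collapse probes first with collapse_probes()",
          dataset_id)
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids in dataset '%s'", dataset_id)
  if (!all(is.finite(values)))
    stopf("dataset '%s' contains non-finite expression values", dataset_id)
  group <- as.character(group)
  if (length(group) != ncol(values))
    stopf("group has length %d but dataset '%s' has %d samples",
          length(group), dataset_id, ncol(values))
  if (!all(group %in% c("case", "control")))
    stopf("group labels must be 'case' or 'control'; got: %s",
          paste(unique(setdiff(group, c("case", "control"))), collapse = ", "))
  if (sum(group == "case") < 2L || sum(group == "control") < 2L)
    stopf("dataset '%s' needs at least 2 samples per group (found %d case, %d control)",
          dataset_id, sum(group == "case"), sum(group == "control"))
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight < 0)
    stopf("weight must be a single non-negative number")
  structure(
    list(dataset_id = dataset_id, values = values,
         group = stats::setNames(group, colnames(values)),
         weight = as.numeric(weight)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s'> %d genes x %d samples (%d case / %d control), weight %g\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control"), x$weight))
  invisible(x)
}

#' Gene identifiers of a dataset
#' @param dataset an \code{expression_dataset}
#' @return character vector of gene ids
#' @export
dataset_genes <- function(dataset) rownames(dataset$values)

#' Read an expression matrix with its sample-group file
#'
#' The matrix file is tab-separated text: a header row of sample ids (first
#' column named arbitrarily, e.g. \code{gene}), then one row per gene with
#' the gene id in the first column. The companion group file has two
#' tab-separated columns \code{sample} and \code{group}, mapping every
#' sample to \code{case} or \code{control}.
#'
#' @param matrix_path path to the expression TSV.
#' @param groups_path path to the two-column sample-group TSV.
#' @param dataset_id label for the study.
#' @param weight dataset weight (default 1).
#' @param log2_transform if TRUE, apply log2(x + 1) on read; values are
#'   otherwise assumed to be already log2 scale.
#' @return an \code{expression_dataset}
#' @export
read_expression_matrix <- function(matrix_path, groups_path, dataset_id,
                                   weight = 1, log2_transform = FALSE) {
  if (!file.exists(matrix_path)) stopf("matrix file not found: %s", matrix_path)
  if (!file.exists(groups_path)) stopf("group file not found: %s", groups_path)
  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stopf("matrix file %s has no sample columns", matrix_path)
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stopf("duplicate gene id '%s' in %s; collapse probes first with collapse_probes()",
          genes[duplicated(genes)][1L], matrix_path)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
          vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
          colnames(vals)[bad[1L, 2L]], matrix_path)
  if (anyNA(num))
    stopf("missing values are not supported (first at gene '%s' in %s)",
          genes[which(rowSums(is.na(num)) > 0)[1L]], matrix_path)
  grp <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("sample", "group") %in% colnames(grp)))
    stopf("group file %s must have columns 'sample' and 'group'", groups_path)
  missing <- setdiff(colnames(num), grp$sample)
  if (length(missing) > 0L)
    stopf("sample '%s' in %s has no group label in %s",
          missing[1L], matrix_path, groups_path)
  group <- tolower(grp$group[match(colnames(num), grp$sample)])
  if (log2_transform) {
    if (any(num < 0)) stopf("log2_transform requires non-negative values")
    num <- log2(num + 1)
  }
  expression_dataset(dataset_id, num, group, weight)
}

#' Write an expression dataset as matrix + group TSV files
#'
#' Inverse of \code{\link{read_expression_matrix}}: full floating precision,
#' UTF-8, Unix newlines, so read-after-write is the identity.
#'
#' @param dataset an \code{expression_dataset}
#' @param matrix_path,groups_path output paths
#' @return invisibly, c(matrix_path, groups_path)
#' @export
write_expression_matrix <- function(dataset, matrix_path, groups_path) {
  df <- data.frame(gene = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_full(df, matrix_path)
  write_tsv_full(data.frame(sample = names(dataset$group),
                            group = unname(dataset$group),
                            stringsAsFactors = FALSE),
                 groups_path)
  invisible(c(matrix_path, groups_path))
}

#' Collapse a probe-level matrix to gene level
#'
#' Implements the probe-handling rules used for multi-platform integration:
#' probes with no mapped gene are dropped; a probe mapped to several genes
#' donates its expression row to every one of them; when several probes map
#' to one gene, the gene receives the row of the probe with the largest mean
#' expression across samples (ties broken by lexicographically smallest
#' probe id, for determinism).
#'
#' @param probe_matrix numeric matrix, probes in rows (unique rownames),
#'   samples in columns.
#' @param mapping named list: probe id -> character vector of gene ids
#'   (possibly empty). Probes absent from the mapping are treated as
#'   unmapped and dropped.
#' @return numeric gene-by-sample matrix with unique gene rownames, ordered
#'   lexicographically.
#' @export
collapse_probes <- function(probe_matrix, mapping) {
  if (!is.matrix(probe_matrix) || !is.numeric(probe_matrix))
    stopf("probe_matrix must be a numeric matrix")
  if (is.null(rownames(probe_matrix)) || anyDuplicated(rownames(probe_matrix)))
    stopf("probe_matrix must have unique probe rownames")
  if (!is.list(mapping)) stopf("mapping must be a named list of gene-id vectors")
  probes <- rownames(probe_matrix)
  pairs <- lapply(probes, function(p) {
    g <- unique(as.character(mapping[[p]]))
    g <- g[nzchar(g)]
    if (length(g) == 0L) return(NULL)
    data.frame(probe = p, gene = g, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stopf("no probe mapped to any gene: collapse would produce an empty matrix")
  probe_mean <- rowMeans(probe_matrix)
  # per gene: probe with maximal mean, ties to smallest probe id
  ord <- order(pairs$gene, -probe_mean[pairs$probe], pairs$probe)
  pairs <- pairs[ord, , drop = FALSE]
  keep <- pairs[!duplicated(pairs$gene), , drop = FALSE]
  out <- probe_matrix[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  out[order(rownames(out)), , drop = FALSE]
}
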