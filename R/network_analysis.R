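# Signature-induced interaction subnetwork and hub calling.
#
# Edges come from a STRING-like scored edge list. Only interactions whose
# BOTH endpoints lie in the signature are kept; nodes are the endpoints of
# kept edges (so every node has degree >= 1), and signature genes without a
# kept edge are reported separately as isolates. Hubs are nodes with degree
# strictly above a threshold (default > 10).

#' Read a scored edge list
#'
#' Three tab-separated columns (gene_a, gene_b, score), with or without a
#' header line. Edges below \code{min_score} are dropped; duplicate
#' undirected pairs are collapsed keeping the maximum score; self-loops
#' are dropped with a warning.
#'
#' @param path file path
#' @param min_score confidence threshold in [0, 1]; the default 0.4 is the
#'   conventional STRING medium-confidence cut.
#' @return data.frame of class \code{edge_list} with columns
#'   \code{gene_a}, \code{gene_b} (gene_a < gene_b), \code{score}.
#' @export
read_edge_list <- function(path, min_score = 0.4) {
  if (!file.exists(path)) stopf("edge-list file not found: %s", path)
  if (min_score < 0 || min_score > 1) stopf("min_score must lie in [0, 1]")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("edge-list file %s is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) start <- 2L  # header
  if (start > length(lines))
    return(structure(data.frame(gene_a = character(), gene_b = character(),
                                score = numeric(), stringsAsFactors = FALSE),
                     class = c("edge_list", "data.frame")))
  rows <- fields[start:length(fields)]
  nf <- lengths(rows)
  if (any(nf != 3L))
    stopf("edge-list parse error at line %d of %s: expected 3 tab-separated fields, got %d",
          which(nf != 3L)[1L] + start - 1L, path, nf[nf != 3L][1L])
  a <- vapply(rows, `[`, character(1), 1L)
  b <- vapply(rows, `[`, character(1), 2L)
  score <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 3L)))
  if (anyNA(score))
    stopf("edge-list parse error at line %d of %s: non-numeric score",
          which(is.na(score))[1L] + start - 1L, path)
  loops <- a == b
  if (any(loops)) {
    warnf("%d self-loop(s) dropped from %s", sum(loops), path)
    a <- a[!loops]; b <- b[!loops]; score <- score[!loops]
  }
  ed <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b), score = score,
                   stringsAsFactors = FALSE)
  # collapse duplicate undirected pairs, keep the maximum score
  key <- paste(ed$gene_a, ed$gene_b, sep = "\r")
  ed <- ed[order(key, -ed$score), , drop = FALSE]
  ed <- ed[!duplicated(paste(ed$gene_a, ed$gene_b, sep = "\r")), , drop = FALSE]
  ed <- ed[ed$score >= min_score, , drop = FALSE]
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  structure(ed, class = c("edge_list", "data.frame"))
}

#' Write an edge list as three-column TSV (with header)
#' @param edges an \code{edge_list}
#' @param path output path
#' @return invisibly, the path
#' @export
write_edge_list <- function(edges, path) write_tsv_full(as.data.frame(edges), path)

#' Induce the signature subnetwork
#'
#' Keeps exactly the edges whose both endpoints belong to the signature.
#' Nodes are the endpoints of kept edges, hence all have degree >= 1;
#' signature genes with no kept edge are returned as \code{isolates}.
#'
#' @param edges an \code{edge_list} (or data.frame with gene_a, gene_b,
#'   score).
#' @param signature a \code{signature} data.frame or character vector.
#' @return list of class \code{induced_network}: \code{edges} (kept
#'   edges), \code{nodes} (character), \code{degree} (named integer),
#'   \code{isolates} (character).
#' @export
induce_subnetwork <- function(edges, signature) {
  genes <- if (is.data.frame(signature)) signature$gene else as.character(signature)
  genes <- unique(genes)
  if (length(genes) == 0L) stopf("signature is empty")
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b") %in% colnames(edges)))
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes
  kept <- as.data.frame(edges)[keep, , drop = FALSE]
  rownames(kept) <- NULL
  ends <- c(kept$gene_a, kept$gene_b)
  deg <- table(factor(ends, levels = sort(unique(ends))))
  deg <- stats::setNames(as.integer(deg), names(deg))
  structure(list(edges = kept, nodes = names(deg), degree = deg,
                 isolates = sort(setdiff(genes, names(deg)))),
            class = "induced_network")
}

#' @export
print.induced_network <- function(x, ...) {
  cat(sprintf("<induced_network> %d nodes, %d edges, %d signature isolates\n",
              length(x$nodes), nrow(x$edges), length(x$isolates)))
  invisible(x)
}

#' Degree table of an induced network
#'
#' Degree counts distinct neighbours (the graph is simple by
#' construction). Sorted by degree descending, ties by gene id ascending.
#'
#' @param network an \code{\link{induce_subnetwork}} result
#' @return data.frame with columns \code{gene}, \code{degree}
#' @export
compute_degrees <- function(network) {
  stopifnot(inherits(network, "induced_network"))
  df <- data.frame(gene = names(network$degree),
                   degree = unname(network$degree), stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Identify hub genes
#'
#' Hubs are genes whose degree is strictly greater than the threshold
#' (default 10), returned in degree-descending order.
#'
#' @param degrees a \code{\link{compute_degrees}} table
#' @param threshold integer >= 0 (default 10)
#' @return data.frame with columns \code{gene}, \code{degree}, the hubs
#'   only
#' @export
identify_hubs <- function(degrees, threshold = 10L) {
  stopifnot(is.data.frame(degrees), all(c("gene", "degree") %in% colnames(degrees)))
  if (threshold < 0) stopf("threshold must be >= 0")
  out <- degrees[degrees$degree > threshold, , drop = FALSE]
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network as Cytoscape SIF
#'
#' One line per edge: \code{geneA<TAB>pp<TAB>geneB}.
#'
#' @param network an \code{induced_network}
#' @param path output path
#' @return invisibly, the path
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "induced_network"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(network$edges$gene_a, "pp", network$edges$gene_b, sep = "\t"),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write node attributes (gene, degree, is_hub) as TSV
#'
#' @param network an \code{induced_network}
#' @param path output path
#' @param threshold hub threshold passed to \code{\link{identify_hubs}}
#' @return invisibly, the path
#' @export
write_node_attributes <- function(network, path, threshold = 10L) {
  deg <- compute_degrees(network)
  deg$is_hub <- deg$degree > threshold
  write_tsv_full(deg, path)
}
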