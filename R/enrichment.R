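# Gene-set enrichment of the signature: one-sided hypergeometric
# (Fisher-exact) p-values, the conservative EASE variant (overlap reduced
# by one), BH FDR across tested sets, and the literal significance filters
# of the two profiles: "go" requires overlap k > 5 and EASE p < 0.01,
# "kegg" requires k > 2 and EASE p < 0.05 (both strict).

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated — set id, description,
#' then member gene ids. Duplicate members within a set are deduplicated
#' with a warning; a duplicate set id is an error.
#'
#' @param path GMT file path
#' @return a \code{gene_set_collection}: list with \code{sets} (named list
#'   of unique member vectors) and \code{descriptions} (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopf("GMT parse error at line %d of %s: need id, description and >= 1 member",
            i, path)
    id <- f[1L]
    if (id %in% names(sets)) stopf("duplicate set id '%s' at line %d of %s", id, i, path)
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warnf("set '%s' has duplicate members; deduplicated", id)
      members <- unique(members)
    }
    sets[[id]] <- members
    desc[[id]] <- f[2L]
  }
  structure(list(sets = sets, descriptions = desc), class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a \code{gene_set_collection}
#' @param path output path
#' @return invisibly, the path
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  ids <- names(collection$sets)
  writeLines(vapply(ids, function(id)
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t"), character(1)),
    con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' 2x2 overlap counts for one gene set
#'
#' @param N background universe size
#' @param n signature genes within the background
#' @param K set members within the background
#' @param k overlap between signature and set
#' @return validated list of class \code{contingency_counts}
#' @export
contingency_counts <- function(N, n, K, k) {
  v <- c(N = N, n = n, K = K, k = k)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stopf("counts must be non-negative integers")
  if (n > N || K > N) stopf("n (%d) and K (%d) must not exceed N (%d)", n, K, N)
  if (k > min(n, K)) stopf("k (%d) exceeds min(n, K) = %d", k, min(n, K))
  structure(lapply(as.list(v), as.integer), class = "contingency_counts")
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' X counts the overlap between a random n-subset of an N-gene background
#' and a fixed K-gene set; the one-sided Fisher exact enrichment p-value.
#' Computed via the stable log-space tail of \code{phyper}.
#'
#' @param counts a \code{\link{contingency_counts}}
#' @return p-value in [0, 1]
#' @export
hypergeometric_tail <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  if (counts$k == 0L) return(1)
  stats::phyper(counts$k - 1L, counts$K, counts$N - counts$K, counts$n,
                lower.tail = FALSE)
}

#' EASE score: conservative modified Fisher exact p-value
#'
#' The upper-tail hypergeometric p recomputed with the observed overlap
#' reduced by one (k - 1), so one supporting gene is discounted; k <= 1
#' maps to p = 1. Always >= the plain Fisher p.
#'
#' @param counts a \code{\link{contingency_counts}}
#' @return p-value in [0, 1]
#' @export
ease_p <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  if (counts$k <= 1L) return(1)
  hypergeometric_tail(contingency_counts(counts$N, counts$n, counts$K,
                                         counts$k - 1L))
}

#' Enrich a signature against a gene-set collection
#'
#' Each set is reduced to its members inside the background universe and
#' tested for overlap with the signature. Significance follows the active
#' profile applied to the EASE score: \code{"go"} requires k > 5 and
#' p_ease < 0.01; \code{"kegg"} requires k > 2 and p_ease < 0.05 (strict
#' inequalities). BH FDR over the EASE p-values of all tested sets is
#' reported but not used for the flag.
#'
#' @param signature a \code{signature} data.frame or character vector of
#'   gene ids.
#' @param collection a \code{gene_set_collection}.
#' @param profile \code{"go"} or \code{"kegg"}.
#' @param background character vector of background genes; defaults to the
#'   union of all set members and the signature. In the pipeline the
#'   common-gene intersection is passed explicitly.
#' @return data.frame of class \code{enrichment_table}, one row per set
#'   with members in the background, sorted ascending by \code{p_ease}:
#'   \code{set_id}, \code{description}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p_fisher}, \code{p_ease}, \code{fdr},
#'   \code{significant}.
#' @export
enrich_signature <- function(signature, collection, profile = c("go", "kegg"),
                             background = NULL) {
  profile <- match.arg(profile)
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- if (is.data.frame(signature)) signature$gene else as.character(signature)
  genes <- unique(genes)
  if (length(genes) == 0L) stopf("signature is empty")
  if (is.null(background))
    background <- sort(unique(c(unlist(collection$sets, use.names = FALSE), genes)))
  outside <- setdiff(genes, background)
  if (length(outside) > 0L) {
    warnf("%d signature genes outside the background were dropped", length(outside))
    genes <- intersect(genes, background)
    if (length(genes) == 0L) stopf("no signature gene lies in the background")
  }
  N <- length(background); n <- length(genes)
  min_k <- if (profile == "go") 5L else 2L
  max_p <- if (profile == "go") 0.01 else 0.05
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], background)
    if (length(members) == 0L) return(NULL)
    k <- length(intersect(members, genes))
    cc <- contingency_counts(N, n, length(members), k)
    data.frame(set_id = id,
               description = unname(collection$descriptions[[id]]),
               k = k, K = length(members), n = n, N = N,
               p_fisher = hypergeometric_tail(cc), p_ease = ease_p(cc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no gene set intersects the background")
  out$fdr <- stats::p.adjust(out$p_ease, method = "BH")
  out$significant <- out$k > min_k & out$p_ease < max_p
  out <- out[order(out$p_ease, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"), profile = profile)
}

#' Write an enrichment table as TSV
#' @param table an \code{enrichment_table}
#' @param path output path
#' @return invisibly, the path
#' @export
write_enrichment <- function(table, path) write_tsv_full(as.data.frame(table), path)
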