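# Multi-study simulator with planted ground truth.
#
# Emulates the three-study case/control design the pipeline targets: a
# shared gene universe present in every study, dataset-private genes that
# exist only to exercise the intersection step, planted differentially
# expressed (DE) genes with configurable log2 effects, Gaussian noise on
# the log2 scale, plus generators for gene-set collections with one planted
# enriched set and interaction networks with planted high-degree hubs.

#' Simulation configuration
#'
#' @param n_datasets number of studies (>= 1).
#' @param genes_per_dataset integer vector of length \code{n_datasets}:
#'   total genes in each study (shared + private).
#' @param shared_gene_fraction proportion in (0, 1] of the smallest study's
#'   gene count forming the shared universe; the shared universe size is
#'   \code{round(shared_gene_fraction * min(genes_per_dataset))} and the
#'   cross-study intersection equals it exactly.
#' @param n_cases,n_controls per-dataset sample counts (>= 2 each).
#' @param n_de number of planted DE genes, all drawn from the shared
#'   universe (>= 0).
#' @param effect_size mean absolute log2 fold change of planted genes.
#' @param effect_sd spread (sd) of planted absolute effects.
#' @param noise_sd residual standard deviation, log2 units (>= 0).
#' @param seed integer random seed; fixed seed gives bit-identical output.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(n_datasets = 3L,
                              genes_per_dataset = c(3750L, 4000L, 4500L),
                              shared_gene_fraction = 0.8,
                              n_cases = 10L, n_controls = 10L,
                              n_de = 150L,
                              effect_size = 2.0, effect_sd = 0.5,
                              noise_sd = 1.0, seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              genes_per_dataset = as.integer(genes_per_dataset),
              shared_gene_fraction = as.numeric(shared_gene_fraction),
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_de = as.integer(n_de),
              effect_size = as.numeric(effect_size),
              effect_sd = as.numeric(effect_sd),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  if (cfg$n_datasets < 1L) stopf("n_datasets must be >= 1")
  if (length(cfg$genes_per_dataset) != cfg$n_datasets)
    stopf("genes_per_dataset must have length n_datasets (%d), got %d",
          cfg$n_datasets, length(cfg$genes_per_dataset))
  if (any(cfg$genes_per_dataset < 1L)) stopf("genes_per_dataset must be >= 1")
  if (!(cfg$shared_gene_fraction > 0 && cfg$shared_gene_fraction <= 1))
    stopf("shared_gene_fraction must lie in (0, 1]")
  if (cfg$n_cases < 2L || cfg$n_controls < 2L)
    stopf("n_cases and n_controls must each be >= 2")
  if (cfg$n_de < 0L) stopf("n_de must be >= 0")
  if (cfg$noise_sd < 0 || cfg$effect_sd < 0)
    stopf("noise_sd and effect_sd must be >= 0")
  n_shared <- n_shared_genes(cfg)
  if (cfg$n_de > n_shared)
    stopf("n_de (%d) exceeds the shared gene universe size (%d)",
          cfg$n_de, n_shared)
  class(cfg) <- "simulation_config"
  cfg
}

n_shared_genes <- function(config)
  as.integer(round(config$shared_gene_fraction * min(config$genes_per_dataset)))

#' Generate multi-study expression data with planted DE genes
#'
#' Model: each shared gene g gets one global baseline b_g ~ N(7, 1.5^2)
#' (log2 intensity scale typical of processed arrays); each dataset adds a
#' scalar baseline shift ~ N(0, 0.5^2) standing in for study-level batch
#' differences; samples add iid N(0, noise_sd^2) noise. Planted genes shift
#' the case-group mean by a signed effect: sign +/- with equal probability,
#' magnitude ~ N(effect_size, effect_sd^2) truncated below at 0, identical
#' in every dataset. Dataset-private genes are pure noise and carry
#' dataset-specific ids so the cross-study intersection is exactly the
#' shared universe.
#'
#' @param config a \code{\link{simulation_config}}
#' @return list with \code{datasets} (list of \code{expression_dataset})
#'   and \code{truth} (list: \code{de_genes}, \code{effects} named signed
#'   log2 effects, \code{shared_genes}, \code{seed}).
#' @export
generate_multistudy_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_shared <- n_shared_genes(config)
  shared <- sprintf("G%05d", seq_len(n_shared))
  de_genes <- sort(sample(shared, config$n_de))
  signs <- sample(c(-1, 1), config$n_de, replace = TRUE)
  mags <- pmax(stats::rnorm(config$n_de, config$effect_size, config$effect_sd), 0)
  effects <- stats::setNames(signs * mags, de_genes)
  baseline <- stats::setNames(stats::rnorm(n_shared, 7, 1.5), shared)

  datasets <- vector("list", config$n_datasets)
  for (j in seq_len(config$n_datasets)) {
    n_priv <- config$genes_per_dataset[j] - n_shared
    priv <- if (n_priv > 0L) sprintf("D%d_P%05d", j, seq_len(n_priv)) else character()
    genes <- c(shared, priv)
    base_j <- c(baseline[shared],
                stats::setNames(stats::rnorm(length(priv), 7, 1.5), priv)) +
      stats::rnorm(1, 0, 0.5)
    n_samp <- config$n_cases + config$n_controls
    group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
    samples <- sprintf("%s_S%02d", c("CASE", "CTRL")[(group == "control") + 1L],
                       c(seq_len(config$n_cases), seq_len(config$n_controls)))
    vals <- matrix(base_j, nrow = length(genes), ncol = n_samp,
                   dimnames = list(genes, samples))
    if (config$n_de > 0L)
      vals[de_genes, group == "case"] <-
        vals[de_genes, group == "case"] + effects
    vals <- vals + matrix(stats::rnorm(length(genes) * n_samp, 0, config$noise_sd),
                          nrow = length(genes))
    datasets[[j]] <- expression_dataset(sprintf("SIM%d", j), vals, group, 1)
  }
  list(datasets = datasets,
       truth = list(de_genes = de_genes, effects = effects,
                    shared_genes = shared, seed = config$seed))
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Exactly one set (the planted one, id \code{"SET_PLANTED"}) draws
#' \code{round(signal_fraction * set_size)} members from the planted DE
#' genes and the rest uniformly from the non-DE universe; all other sets
#' are drawn uniformly from the whole universe.
#'
#' @param truth ground-truth list from
#'   \code{\link{generate_multistudy_expression}} (needs \code{de_genes}).
#' @param universe character vector of background gene ids.
#' @param n_sets number of sets (>= 1).
#' @param set_size members per set.
#' @param signal_fraction proportion in [0, 1] of the planted set drawn
#'   from DE genes.
#' @param seed integer seed.
#' @return a \code{gene_set_collection} (see \code{\link{read_gmt}}) with
#'   attribute \code{planted_set_id}.
#' @export
generate_gene_set_collection <- function(truth, universe, n_sets = 50L,
                                         set_size = 50L, signal_fraction = 0.8,
                                         seed = 1L) {
  if (set_size > length(universe))
    stopf("set_size (%d) exceeds universe size (%d)", set_size, length(universe))
  if (signal_fraction < 0 || signal_fraction > 1)
    stopf("signal_fraction must lie in [0, 1]")
  de <- intersect(truth$de_genes, universe)
  n_signal <- as.integer(round(signal_fraction * set_size))
  if (n_signal > length(de))
    stopf("signal_fraction * set_size (%d) exceeds the number of DE genes in the universe (%d)",
          n_signal, length(de))
  non_de <- setdiff(universe, de)
  if (set_size - n_signal > length(non_de))
    stopf("not enough non-DE genes (%d) for %d background members",
          length(non_de), set_size - n_signal)
  set.seed(seed)
  sets <- vector("list", n_sets)
  ids <- c("SET_PLANTED", sprintf("SET%03d", seq_len(max(n_sets - 1L, 0L))))
  sets[[1L]] <- sort(c(sample(de, n_signal), sample(non_de, set_size - n_signal)))
  if (n_sets > 1L)
    for (s in 2:n_sets) sets[[s]] <- sort(sample(universe, set_size))
  names(sets) <- ids[seq_len(n_sets)]
  structure(
    list(sets = sets,
         descriptions = stats::setNames(
           ifelse(names(sets) == "SET_PLANTED", "planted enriched set",
                  "background set"), names(sets))),
    class = "gene_set_collection", planted_set_id = "SET_PLANTED")
}

#' Generate an interaction network with planted hubs
#'
#' Builds an undirected simple graph over the union of signature and
#' background genes. \code{n_hubs} genes sampled from the signature are
#' each wired to \code{hub_degree} distinct other signature genes;
#' additional edges between any gene pair appear independently with
#' probability \code{background_edge_prob}. Every edge carries a
#' STRING-like combined confidence score drawn uniform in (0.4, 1].
#'
#' @param signature_genes character vector (the planted hubs and their
#'   neighbours come from here).
#' @param background_genes character vector of additional node candidates.
#' @param n_hubs number of planted hubs (<= length(signature_genes)).
#' @param hub_degree edges forced per hub
#'   (<= length(signature_genes) - 1).
#' @param background_edge_prob per-pair background edge probability.
#' @param seed integer seed.
#' @return a data.frame edge list (gene_a, gene_b, score) of class
#'   \code{edge_list}, with attribute \code{planted_hubs}.
#' @export
generate_interaction_network <- function(signature_genes, background_genes = character(),
                                         n_hubs = 5L, hub_degree = 15L,
                                         background_edge_prob = 0.005, seed = 1L) {
  signature_genes <- unique(as.character(signature_genes))
  background_genes <- setdiff(unique(as.character(background_genes)), signature_genes)
  if (n_hubs > length(signature_genes))
    stopf("n_hubs (%d) exceeds the signature size (%d)", n_hubs,
          length(signature_genes))
  if (hub_degree > length(signature_genes) - 1L)
    stopf("hub_degree (%d) exceeds signature size - 1 (%d)", hub_degree,
          length(signature_genes) - 1L)
  if (background_edge_prob < 0 || background_edge_prob > 1)
    stopf("background_edge_prob must lie in [0, 1]")
  set.seed(seed)
  hubs <- sort(sample(signature_genes, n_hubs))
  edges <- list()
  for (h in hubs) {
    nbrs <- sample(setdiff(signature_genes, h), hub_degree)
    edges[[h]] <- data.frame(gene_a = pmin(h, nbrs), gene_b = pmax(h, nbrs),
                             stringsAsFactors = FALSE)
  }
  all_genes <- sort(c(signature_genes, background_genes))
  if (background_edge_prob > 0 && length(all_genes) >= 2L) {
    pair_idx <- utils::combn(length(all_genes), 2L)
    hit <- stats::runif(ncol(pair_idx)) < background_edge_prob
    if (any(hit))
      edges[["background"]] <- data.frame(
        gene_a = all_genes[pair_idx[1L, hit]],
        gene_b = all_genes[pair_idx[2L, hit]],
        stringsAsFactors = FALSE)
  }
  ed <- unique(do.call(rbind, edges))
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  ed$score <- 0.4 + stats::runif(nrow(ed)) * 0.6
  structure(ed, class = c("edge_list", "data.frame"), planted_hubs = hubs)
}
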