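# End-to-end orchestration from one JSON configuration file.
#
# Stage order: read or simulate datasets -> per-dataset DE tables ->
# common-gene intersection -> per-dataset fold-change ranks -> GWRS/GWGS
# -> top-K signature -> enrichment per profile -> induced interaction
# network -> hubs. Every stage writes its table; a JSON manifest records
# inputs, parameters, the seed, output files and stage row counts.
# Identical config + seed gives byte-identical outputs.

pipeline_defaults <- function() list(
  k = 200L,                      # signature size ("top 200")
  seed = 1L,
  log2_transform = FALSE,        # apply log2(x+1) on read
  apply_deg_filter = FALSE,      # restrict ranking to p<0.05 & FDR<0.05 genes
  deg_p = 0.05, deg_fdr = 0.05,
  min_score = 0.4,               # STRING-like edge confidence cut
  hub_threshold = 10L,           # hubs have degree strictly above this
  enrichment_profiles = c("go", "kegg"))

known_keys <- c("datasets", "simulation", "gene_sets_gmt", "edge_list",
                "output_dir", names(pipeline_defaults()))

#' Validate and default a pipeline configuration
#'
#' The configuration is a JSON object (or an equivalent R list). It must
#' contain either a \code{datasets} array (entries with
#' \code{id}, \code{matrix}, \code{groups} paths and optional
#' \code{weight}) or a \code{simulation} block (fields of
#' \code{\link{simulation_config}}), not neither. Optional keys:
#' \code{gene_sets_gmt} (path), \code{edge_list} (path),
#' \code{output_dir}, \code{k}, \code{seed}, \code{log2_transform},
#' \code{apply_deg_filter}, \code{min_score}, \code{hub_threshold},
#' \code{enrichment_profiles}. Unknown keys are rejected; all problems are
#' reported at once. Dataset weights are normalised to sum to 1.
#'
#' @param path path to a JSON config file, or a list already in memory.
#' @return a validated \code{pipeline_config} list with defaults filled.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (is.list(path)) path else stopf("config must be a path or a list")
  problems <- character()
  unknown <- setdiff(names(cfg), known_keys)
  if (length(unknown) > 0L)
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  has_data <- !is.null(cfg$datasets) && length(cfg$datasets) > 0L
  has_sim <- !is.null(cfg$simulation)
  if (!has_data && !has_sim)
    problems <- c(problems, "config needs either 'datasets' or a 'simulation' block")
  if (has_data && has_sim)
    problems <- c(problems, "'datasets' and 'simulation' are mutually exclusive")
  defaults <- pipeline_defaults()
  for (key in names(defaults))
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  if (!is.numeric(cfg$k) || length(cfg$k) != 1L || cfg$k < 1)
    problems <- c(problems, "'k' must be a single integer >= 1")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    problems <- c(problems, "'seed' must be a single integer")
  if (!is.numeric(cfg$min_score) || cfg$min_score < 0 || cfg$min_score > 1)
    problems <- c(problems, "'min_score' must lie in [0, 1]")
  if (!is.numeric(cfg$hub_threshold) || cfg$hub_threshold < 0)
    problems <- c(problems, "'hub_threshold' must be >= 0")
  if (!all(cfg$enrichment_profiles %in% c("go", "kegg")))
    problems <- c(problems, "'enrichment_profiles' entries must be 'go' or 'kegg'")
  if (has_data) {
    ds <- cfg$datasets
    if (is.data.frame(ds)) ds <- split(ds, seq_len(nrow(ds)))
    ds <- lapply(ds, as.list)
    for (i in seq_along(ds)) {
      for (f in c("id", "matrix", "groups"))
        if (is.null(ds[[i]][[f]]))
          problems <- c(problems, sprintf("dataset entry %d lacks '%s'", i, f))
      if (is.null(ds[[i]]$weight)) ds[[i]]$weight <- 1
      if (ds[[i]]$weight < 0)
        problems <- c(problems, sprintf("dataset entry %d has negative weight", i))
    }
    wsum <- sum(vapply(ds, function(d) as.numeric(d$weight), numeric(1)))
    if (wsum <= 0) {
      problems <- c(problems, "dataset weights must not all be zero")
    } else {
      for (i in seq_along(ds)) ds[[i]]$weight <- as.numeric(ds[[i]]$weight) / wsum
    }
    cfg$datasets <- ds
  }
  if (has_sim) {
    # the master seed drives the simulation unless the block sets its own
    if (is.list(cfg$simulation) && is.null(cfg$simulation$seed) &&
        is.numeric(cfg$seed))
      cfg$simulation$seed <- cfg$seed
    sim_try <- tryCatch(do.call(simulation_config, as.list(cfg$simulation)),
                        error = function(e) conditionMessage(e))
    if (is.character(sim_try)) {
      problems <- c(problems, sprintf("simulation block invalid: %s", sim_try))
    } else cfg$simulation <- sim_try
  }
  if (length(problems) > 0L)
    stopf("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  cfg$k <- as.integer(cfg$k)
  cfg$seed <- as.integer(cfg$seed)
  cfg$hub_threshold <- as.integer(cfg$hub_threshold)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full integration pipeline
#'
#' @param config a \code{\link{validate_config}} result, a config list, or
#'   a path to a JSON config file.
#' @param output_dir overrides the config's output directory.
#' @param verbose log stage progress and filter before/after counts.
#' @return the manifest list (also written to
#'   \code{<output_dir>/manifest.json}): parameters, seed, per-stage row
#'   counts and the output file list.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  outdir <- if (!is.null(output_dir)) output_dir else config$output_dir
  if (is.null(outdir)) stopf("no output directory given (config 'output_dir' or argument)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  pars <- config[setdiff(names(config), "datasets")]
  if (!is.null(pars$simulation)) pars$simulation <- unclass(pars$simulation)
  manifest <- list(parameters = pars,
                   seed = config$seed, stages = list(), outputs = character(),
                   status = "running")
  out_file <- function(name) file.path(outdir, name)
  add_out <- function(p) manifest$outputs <<- c(manifest$outputs, basename(p))
  fail <- function(stage, e) {
    manifest$status <<- sprintf("failed at stage '%s'", stage)
    jsonlite::write_json(manifest, out_file("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e) fail(name, e))

  ## stage 1: obtain datasets
  datasets <- stage("input", {
    if (!is.null(config$simulation)) {
      sim <- generate_multistudy_expression(config$simulation)
      truth_path <- out_file("ground_truth.json")
      jsonlite::write_json(
        list(de_genes = sim$truth$de_genes,
             effects = as.list(sim$truth$effects),
             seed = sim$truth$seed),
        truth_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      add_out(truth_path)
      for (d in sim$datasets) {
        mp <- out_file(sprintf("%s_matrix.tsv", d$dataset_id))
        gp <- out_file(sprintf("%s_groups.tsv", d$dataset_id))
        write_expression_matrix(d, mp, gp)
        add_out(mp); add_out(gp)
      }
      manifest$truth <- list(n_de = length(sim$truth$de_genes))
      sim$datasets
    } else {
      lapply(config$datasets, function(d)
        read_expression_matrix(d$matrix, d$groups, d$id, weight = d$weight,
                               log2_transform = isTRUE(config$log2_transform)))
    }
  })
  say("input: %d datasets (%s genes)", length(datasets),
      paste(vapply(datasets, function(d) nrow(d$values), numeric(1)), collapse = "/"))

  ## stage 2: per-dataset DE
  de_tables <- stage("differential_expression", lapply(datasets, compute_de_table))

  ## stage 3: intersection
  common <- stage("intersection", intersect_genes(lapply(datasets, dataset_genes)))
  say("intersection: %d common genes", length(common))
  manifest$stages$intersection <- list(n_common_genes = length(common))

  ## stage 4: ranks + GWRS/GWGS
  integration <- stage("rank_integration", {
    ranked <- lapply(de_tables, function(tab) {
      universe <- common
      if (isTRUE(config$apply_deg_filter)) {
        pass <- tab$gene[tab$p_value < config$deg_p & tab$fdr < config$deg_fdr]
        universe <- intersect(common, pass)
        say("DEG filter (%s): %d -> %d genes", attr(tab, "dataset_id"),
            length(common), length(universe))
        if (length(universe) == 0L)
          stopf("DEG filter removed every common gene in dataset '%s'",
                attr(tab, "dataset_id"))
      }
      rank_by_fold_change(tab, restrict_to = universe)
    })
    if (isTRUE(config$apply_deg_filter)) {
      # re-intersect: ranking universes may now differ across datasets
      universe <- intersect_genes(lapply(ranked, function(r) r$gene))
      ranked <- lapply(seq_along(ranked), function(j)
        rank_by_fold_change(de_tables[[j]], restrict_to = universe))
    }
    for (j in seq_along(de_tables)) {
      p <- out_file(sprintf("%s_de.tsv", datasets[[j]]$dataset_id))
      write_de_table(de_tables[[j]], p, ranked = ranked[[j]])
      add_out(p)
    }
    weights <- vapply(datasets, function(d) d$weight, numeric(1))
    gwgs <- gwgs_scores(gwrs_matrix(ranked), weights)
    p <- out_file("gwgs_table.tsv"); write_gwgs_table(gwgs, p); add_out(p)
    gwgs
  })
  manifest$stages$rank_integration <- list(
    m = nrow(integration), weights = as.numeric(attr(integration, "weights")))

  ## stage 5: signature
  signature <- stage("signature", {
    sig <- select_top_k(integration, config$k)
    p <- out_file("signature.tsv"); write_gwgs_table(sig, p); add_out(p)
    p <- out_file("signature_genes.txt"); write_gene_list(sig, p); add_out(p)
    sig
  })
  say("signature: top %d of %d genes", nrow(signature), nrow(integration))
  manifest$stages$signature <- list(k = nrow(signature))

  ## stage 6: enrichment
  if (!is.null(config$gene_sets_gmt)) {
    enr <- stage("enrichment", {
      collection <- read_gmt(config$gene_sets_gmt)
      res <- list()
      for (prof in config$enrichment_profiles) {
        tab <- enrich_signature(signature, collection, profile = prof,
                                background = common)
        p <- out_file(sprintf("enrichment_%s.tsv", prof))
        write_enrichment(tab, p); add_out(p)
        res[[prof]] <- list(n_sets_tested = nrow(tab),
                            n_significant = sum(tab$significant),
                            top_set = tab$set_id[1L])
        say("enrichment (%s): %d/%d sets significant", prof,
            sum(tab$significant), nrow(tab))
      }
      res
    })
    manifest$stages$enrichment <- enr
  }

  ## stage 7: network + hubs
  if (!is.null(config$edge_list)) {
    net_info <- stage("network", {
      edges <- read_edge_list(config$edge_list, min_score = config$min_score)
      network <- induce_subnetwork(edges, signature)
      degrees <- compute_degrees(network)
      hubs <- identify_hubs(degrees, config$hub_threshold)
      p <- out_file("network.sif"); write_sif(network, p); add_out(p)
      p <- out_file("node_attributes.tsv")
      write_node_attributes(network, p, config$hub_threshold); add_out(p)
      p <- out_file("hubs.tsv"); write_tsv_full(hubs, p); add_out(p)
      say("network: %d nodes, %d edges, %d hubs (degree > %d)",
          length(network$nodes), nrow(network$edges), nrow(hubs),
          config$hub_threshold)
      list(n_nodes = length(network$nodes), n_edges = nrow(network$edges),
           n_isolates = length(network$isolates), n_hubs = nrow(hubs),
           hubs = hubs$gene)
    })
    manifest$stages$network <- net_info
  }

  manifest$status <- "ok"
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$outputs <- c(manifest$outputs, "manifest.json")
  invisible(manifest)
}
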