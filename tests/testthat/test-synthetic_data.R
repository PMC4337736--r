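test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_de = 4000), "exceeds the shared gene universe")
  expect_error(simulation_config(shared_gene_fraction = 0), "shared_gene_fraction")
  expect_error(simulation_config(n_cases = 1), "at least|>= 2")
  expect_error(simulation_config(genes_per_dataset = c(100, 100)), "length n_datasets")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
})

test_that("expression generator honours its construction contract", {
  # no planted signal: empty truth, equal population means by construction
  cfg0 <- simulation_config(genes_per_dataset = c(100L, 120L, 110L),
                            shared_gene_fraction = 0.5, n_de = 0L, seed = 3L)
  sim0 <- generate_multistudy_expression(cfg0)
  expect_length(sim0$truth$de_genes, 0L)

  # noiseless single planted gene: case - control difference is the effect,
  # exactly, in every dataset
  cfg1 <- simulation_config(n_datasets = 2L, genes_per_dataset = c(50L, 50L),
                            shared_gene_fraction = 1, n_de = 1L,
                            effect_size = 2, effect_sd = 0, noise_sd = 0,
                            seed = 9L)
  sim1 <- generate_multistudy_expression(cfg1)
  g <- sim1$truth$de_genes
  for (d in sim1$datasets) {
    diff <- mean(d$values[g, d$group == "case"]) -
      mean(d$values[g, d$group == "control"])
    expect_equal(abs(diff), 2, tolerance = 1e-12)
    expect_equal(diff, unname(sim1$truth$effects[g]), tolerance = 1e-12)
  }
  # non-planted genes have identical group means when noiseless
  other <- setdiff(rownames(sim1$datasets[[1]]$values), g)[1]
  d <- sim1$datasets[[1]]
  expect_equal(mean(d$values[other, d$group == "case"]),
               mean(d$values[other, d$group == "control"]))
})

test_that("intersection equals the configured shared universe exactly", {
  cfg <- simulation_config(genes_per_dataset = c(200L, 250L, 300L),
                           shared_gene_fraction = 0.6, n_de = 10L, seed = 5L)
  sim <- generate_multistudy_expression(cfg)
  common <- intersect_genes(lapply(sim$datasets, dataset_genes))
  expect_identical(common, sim$truth$shared_genes)
  expect_length(common, round(0.6 * 200))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- simulation_config(genes_per_dataset = c(80L, 90L, 100L),
                           shared_gene_fraction = 0.5, n_de = 8L, seed = 21L)
  a <- generate_multistudy_expression(cfg)
  b <- generate_multistudy_expression(cfg)
  expect_identical(a, b)
  truth <- a$truth
  expect_identical(
    generate_gene_set_collection(truth, truth$shared_genes, 10, 10, 0.5, seed = 2),
    generate_gene_set_collection(truth, truth$shared_genes, 10, 10, 0.5, seed = 2))
  expect_identical(
    generate_interaction_network(truth$shared_genes[1:30], n_hubs = 2,
                                 hub_degree = 5, seed = 7),
    generate_interaction_network(truth$shared_genes[1:30], n_hubs = 2,
                                 hub_degree = 5, seed = 7))
})

test_that("gene-set generator plants exactly one enriched set", {
  cfg <- simulation_config(genes_per_dataset = c(300L, 300L, 300L),
                           shared_gene_fraction = 1, n_de = 40L, seed = 13L)
  truth <- generate_multistudy_expression(cfg)$truth
  universe <- truth$shared_genes

  col <- generate_gene_set_collection(truth, universe, n_sets = 12L,
                                      set_size = 20L, signal_fraction = 0.8,
                                      seed = 4L)
  expect_length(col$sets, 12L)
  expect_true(all(lengths(col$sets) == 20L))
  planted <- col$sets[[attr(col, "planted_set_id")]]
  expect_equal(sum(planted %in% truth$de_genes), round(0.8 * 20))

  # zero signal: planted set has no DE member
  col0 <- generate_gene_set_collection(truth, universe, n_sets = 3L,
                                       set_size = 15L, signal_fraction = 0,
                                       seed = 4L)
  expect_equal(sum(col0$sets[[attr(col0, "planted_set_id")]] %in% truth$de_genes), 0L)

  # size bookkeeping with a single set
  col1 <- generate_gene_set_collection(truth, universe, n_sets = 1L,
                                       set_size = 10L, signal_fraction = 0.5,
                                       seed = 4L)
  expect_length(col1$sets, 1L)
  expect_length(unique(col1$sets[[1]]), 10L)

  expect_error(
    generate_gene_set_collection(truth, universe, n_sets = 2L, set_size = 60L,
                                 signal_fraction = 1, seed = 1L),
    "exceeds the number of DE genes")
})

test_that("network generator builds a simple graph with forced hub degrees", {
  sig <- sprintf("S%02d", 1:40)
  # pure star: one hub, no background edges
  star <- generate_interaction_network(sig, n_hubs = 1L, hub_degree = 15L,
                                       background_edge_prob = 0, seed = 8L)
  expect_equal(nrow(star), 15L)
  hub <- attr(star, "planted_hubs")
  expect_true(all(star$gene_a == hub | star$gene_b == hub))
  expect_true(all(star$score > 0.4 & star$score <= 1))

  # simple-graph invariant on a denser configuration
  net <- generate_interaction_network(sig, sprintf("B%02d", 1:30), n_hubs = 3L,
                                      hub_degree = 10L,
                                      background_edge_prob = 0.05, seed = 8L)
  expect_true(all(net$gene_a != net$gene_b))
  expect_false(anyDuplicated(paste(net$gene_a, net$gene_b)) > 0)
  expect_true(all(net$gene_a < net$gene_b))

  expect_error(generate_interaction_network(sig, n_hubs = 50L, hub_degree = 5L),
               "n_hubs")
  expect_error(generate_interaction_network(sig, n_hubs = 1L, hub_degree = 40L),
               "hub_degree")
})

test_that("with no planted signal, top-K membership is exchangeable across genes", {
  # small two-study null; each gene should enter the top-K with
  # probability K/m (checked within 3 binomial SE over 300 seeds)
  m <- 60L; K <- 10L; n_seeds <- 300L
  hits <- numeric(m)
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(n_datasets = 2L, genes_per_dataset = c(m, m),
                             shared_gene_fraction = 1, n_cases = 4L,
                             n_controls = 4L, n_de = 0L, seed = 5000L + s)
    sim <- generate_multistudy_expression(cfg)
    ranked <- lapply(lapply(sim$datasets, compute_de_table),
                     rank_by_fold_change)
    sig <- select_top_k(gwgs_scores(gwrs_matrix(ranked)), K)
    hits <- hits + (sim$truth$shared_genes %in% sig$gene)
  }
  p_hat <- hits / n_seeds
  se <- sqrt((K / m) * (1 - K / m) / n_seeds)
  expect_true(all(abs(p_hat - K / m) <= 3 * se))
})
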