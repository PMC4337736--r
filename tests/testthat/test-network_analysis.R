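test_that("read_edge_list filters, dedups and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tscore",
               "A\tB\t0.9", "B\tA\t0.7",   # duplicate undirected pair
               "C\tC\t0.8",                 # self-loop
               "B\tC\t0.3"), path)          # below default threshold
  expect_warning(ed <- read_edge_list(path, min_score = 0.4), "self-loop")
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$gene_a, "A"); expect_equal(ed$gene_b, "B")
  expect_equal(ed$score, 0.9)  # max of the duplicate pair

  # headerless files work too; filter saturation empties the list
  writeLines(c("A\tB\t0.9", "B\tC\t0.99"), path)
  expect_equal(nrow(read_edge_list(path, min_score = 0.4)), 2L)
  expect_equal(nrow(read_edge_list(path, min_score = 1.0)), 0L)

  writeLines(c("A\tB\t0.9", "A\tB"), path)
  expect_error(read_edge_list(path), "line 2")

  # round trip, and brute-force filter count on a generated fixture
  ed <- random_edges(40, 0.3, seed = 5)
  write_edge_list(ed, path)
  for (thr in c(0.4, 0.6, 0.9))
    expect_equal(nrow(read_edge_list(path, min_score = thr)),
                 sum(ed$score >= thr))
})

test_that("induce_subnetwork keeps exactly the signature-internal edges", {
  ed <- structure(data.frame(gene_a = c("A", "A", "B", "C"),
                             gene_b = c("B", "C", "C", "D"),
                             score = rep(0.9, 4), stringsAsFactors = FALSE),
                  class = c("edge_list", "data.frame"))
  # triangle fully inside the signature
  net <- induce_subnetwork(ed, c("A", "B", "C"))
  expect_length(net$nodes, 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$degree == 2L))
  expect_length(net$isolates, 0L)

  # empty induction: everything isolate
  net0 <- induce_subnetwork(ed, c("X", "Y"))
  expect_length(net0$nodes, 0L)
  expect_equal(nrow(net0$edges), 0L)
  expect_identical(net0$isolates, c("X", "Y"))

  # signature gene D keeps its C edge only via C's membership
  net2 <- induce_subnetwork(ed, c("C", "D", "E"))
  expect_identical(sort(net2$nodes), c("C", "D"))
  expect_identical(net2$isolates, "E")

  # all-genes signature preserves every edge
  netall <- induce_subnetwork(ed, c("A", "B", "C", "D"))
  expect_equal(nrow(netall$edges), nrow(ed))
  expect_error(induce_subnetwork(ed, character()), "empty")
})

test_that("induction and degrees match a brute-force adjacency recount", {
  for (s in 1:20) {
    ed <- random_edges(60, 0.05, seed = 1200 + s)
    set.seed(3000 + s)
    sig <- sample(sprintf("N%03d", 1:60), 25)
    net <- induce_subnetwork(ed, sig)
    keep <- ed$gene_a %in% sig & ed$gene_b %in% sig
    expect_equal(nrow(net$edges), sum(keep))
    nodes <- sort(unique(c(ed$gene_a[keep], ed$gene_b[keep])))
    expect_identical(net$nodes, nodes)
    if (length(nodes) > 0) {
      oracle <- degree_oracle(ed[keep, ], nodes)
      expect_equal(net$degree[nodes], oracle[nodes])
    }
    # handshake lemma
    expect_equal(sum(net$degree), 2L * nrow(net$edges))
    # edge-order invariance of hubs
    shuf <- ed[sample(nrow(ed)), ]
    net_s <- induce_subnetwork(shuf, sig)
    expect_identical(identify_hubs(compute_degrees(net_s), 2),
                     identify_hubs(compute_degrees(net), 2))
  }
})

test_that("degree table and hub calling follow the strict threshold", {
  # star: center H with 5 leaves
  ed <- structure(data.frame(gene_a = rep("H", 5),
                             gene_b = paste0("L", 1:5),
                             score = rep(0.9, 5), stringsAsFactors = FALSE),
                  class = c("edge_list", "data.frame"))
  net <- induce_subnetwork(ed, c("H", paste0("L", 1:5)))
  deg <- compute_degrees(net)
  expect_identical(deg$gene[1], "H")
  expect_equal(deg$degree[1], 5L)
  expect_true(all(deg$degree[-1] == 1L))

  # threshold is strictly >: degree 10 is excluded
  fake <- data.frame(gene = c("A", "B", "C", "D"),
                     degree = c(28L, 11L, 10L, 9L), stringsAsFactors = FALSE)
  hubs <- identify_hubs(fake, 10)
  expect_identical(hubs$gene, c("A", "B"))
  expect_identical(identify_hubs(fake, 30)$gene, character(0))
  expect_error(identify_hubs(fake, -1), ">= 0")
})

test_that("planted hubs are recovered at the default threshold", {
  sig <- sprintf("S%03d", 1:120)
  net <- generate_interaction_network(sig, n_hubs = 4L, hub_degree = 15L,
                                      background_edge_prob = 0.005, seed = 33L)
  ind <- induce_subnetwork(net, sig)
  hubs <- identify_hubs(compute_degrees(ind), 10)
  expect_setequal(hubs$gene, attr(net, "planted_hubs"))
  # brute-force degree check of the planted hubs
  oracle <- degree_oracle(as.data.frame(net), sort(unique(c(net$gene_a, net$gene_b))))
  expect_true(all(oracle[attr(net, "planted_hubs")] >= 15))
})

test_that("SIF and node-attribute exports are well-formed", {
  ed <- random_edges(20, 0.2, seed = 9)
  net <- induce_subnetwork(ed, sprintf("N%03d", 1:20))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(vapply(strsplit(lines, "\t"), `[`, character(1), 2) == "pp"))
  attrs <- withr::local_tempfile(fileext = ".tsv")
  write_node_attributes(net, attrs, threshold = 3)
  tab <- utils::read.delim(attrs)
  expect_identical(colnames(tab), c("gene", "degree", "is_hub"))
  expect_identical(tab$is_hub, tab$degree > 3)
})
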