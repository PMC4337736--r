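# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive and separate from the package's code paths.

# Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Upper-tail hypergeometric P(X >= k) by summing point masses in log space.
hyper_tail_oracle <- function(N, n, K, k) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Degree recount from an explicit adjacency matrix.
degree_oracle <- function(edges, nodes) {
  adj <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    a <- edges$gene_a[r]; b <- edges$gene_b[r]
    adj[a, b] <- 1L; adj[b, a] <- 1L
  }
  rowSums(adj)
}

# Tiny deterministic two-group dataset.
tiny_dataset <- function(id = "D1", genes = 6L, n_case = 3L, n_ctrl = 3L,
                         seed = 42L, weight = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(genes * (n_case + n_ctrl), 7, 1),
                 nrow = genes,
                 dimnames = list(sprintf("G%02d", seq_len(genes)),
                                 sprintf("S%02d", seq_len(n_case + n_ctrl))))
  expression_dataset(id, vals, rep(c("case", "control"), c(n_case, n_ctrl)),
                     weight)
}

# Random valid contingency counts.
random_counts <- function(seed) {
  set.seed(seed)
  N <- sample(50:3000, 1)
  n <- sample(5:min(300, N), 1)
  K <- sample(5:min(300, N), 1)
  k <- sample(0:min(n, K), 1)
  contingency_counts(N, n, K, k)
}

# Random scored edge list over a gene alphabet.
random_edges <- function(n_genes, edge_prob, seed) {
  set.seed(seed)
  genes <- sprintf("N%03d", seq_len(n_genes))
  pairs <- t(combn(genes, 2))
  hit <- runif(nrow(pairs)) < edge_prob
  structure(data.frame(gene_a = pairs[hit, 1], gene_b = pairs[hit, 2],
                       score = runif(sum(hit), 0.4, 1),
                       stringsAsFactors = FALSE),
            class = c("edge_list", "data.frame"))
}
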