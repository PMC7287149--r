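# Fixture builders shared across test files.  Everything is generated in
# code; no stored data.

gene_ids <- function(n) sprintf("g%03d", seq_len(n))

# random genes x samples matrix with valid dimnames
rand_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(gene_ids(n_genes), sprintf("s%03d", seq_len(n_samples))))
}

# design with s sub-experiments of r replicates over the samples of x
design_for <- function(x, r = 3) {
  m <- ncol(x)
  stopifnot(m %% r == 0)
  as_experiment_design(data.frame(
    sample_id = colnames(x),
    sub_experiment = rep(sprintf("e%02d", seq_len(m / r)), each = r),
    stringsAsFactors = FALSE))
}

# symmetric score matrix with continuous entries
rand_scores <- function(n, seed = 1) {
  set.seed(seed)
  S <- matrix(runif(n * n, -1, 1), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(gene_ids(n), gene_ids(n))
  S
}

# adjacency from an explicit edge list over n genes
adj_from_edges <- function(n, edges) {
  g <- gene_ids(n)
  A <- matrix(0L, n, n, dimnames = list(g, g))
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  A
}

# random adjacency at exactly m edges (uniform over pairs)
rand_adjacency <- function(n, m_edges) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), m_edges), , drop = FALSE]
  g <- gene_ids(n)
  A <- matrix(0L, n, n, dimnames = list(g, g))
  A[pick] <- 1L
  A[pick[, 2:1, drop = FALSE]] <- 1L
  A
}

# two k-cliques joined by a single bridge edge
two_clique_adjacency <- function(k = 10) {
  n <- 2 * k
  A <- matrix(0L, n, n, dimnames = list(gene_ids(n), gene_ids(n)))
  A[1:k, 1:k] <- 1L
  A[(k + 1):n, (k + 1):n] <- 1L
  diag(A) <- 0L
  A[k, k + 1] <- A[k + 1, k] <- 1L
  A
}

# duplicated-pair dataset used for bootstrap tests: n_noise independent
# genes plus one gene duplicated as the last two rows
dup_pair_data <- function(n_noise = 20, n_samples = 60, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n_noise * n_samples), n_noise, n_samples)
  dup <- rnorm(n_samples)
  x <- rbind(base, dup, dup)
  dimnames(x) <- list(gene_ids(n_noise + 2),
                      sprintf("s%03d", seq_len(n_samples)))
  x
}
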