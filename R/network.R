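# Binary network construction at controlled sparsity.
#
# Sparsity omega is the fraction of realized edges among all C(n,2)
# possible gene pairs.  Thresholding is implemented as exact
# order-statistic selection: the floor(omega * M) pairs with largest
# absolute score become edges, which is the fixed point of iteratively
# adjusting the score cut-off alpha until the sparsity is met.

# Enumerate the upper-triangle pairs of a score matrix in the
# deterministic edge-priority order: |score| desc, then row asc, col asc.
rank_pairs <- function(S) {
  ut <- which(upper.tri(S), arr.ind = TRUE)
  sc <- abs(S[ut])
  ord <- order(-sc, ut[, 1L], ut[, 2L])
  list(idx = ut[ord, , drop = FALSE], score = sc[ord])
}

adjacency_from_pairs <- function(idx, genes) {
  A <- matrix(0L, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (nrow(idx)) {
    A[idx] <- 1L
    A[idx[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

#' Threshold a score matrix to a target sparsity
#'
#' Retains, as edges, exactly `floor(omega * M)` gene pairs with the
#' largest absolute scores, where `M = n(n-1)/2`.  The realized cut-off
#' alpha (the smallest retained absolute score) is reported as an
#' attribute.  Ties at the threshold are broken deterministically by
#' sorting pairs on (|score| descending, first gene index ascending,
#' second ascending), so the edge count is exact even on tied or sparse
#' score matrices.
#'
#' @param S Symmetric score matrix with gene dimnames.
#' @param omega Target sparsity, 0 < omega < 1.
#' @return Binary symmetric adjacency matrix with attributes `omega`,
#'   `alpha` (realized cut-off) and `n_edges`.
#' @export
threshold_to_sparsity <- function(S, omega) {
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0 || omega >= 1)
    stop("omega must lie strictly between 0 and 1")
  n <- nrow(S)
  M <- n * (n - 1) / 2
  m_edges <- floor(omega * M + 1e-9)   # guard against 0.005*25200 = 125.99...
  if (m_edges < 1) {
    warning("omega * M < 1: returning an empty network")
    return(structure(adjacency_from_pairs(matrix(0L, 0, 2), rownames(S)),
                     omega = omega, alpha = NA_real_, n_edges = 0L))
  }
  rp <- rank_pairs(S)
  keep <- rp$idx[seq_len(m_edges), , drop = FALSE]
  structure(adjacency_from_pairs(keep, rownames(S)),
            omega = omega, alpha = rp$score[m_edges],
            n_edges = as.integer(m_edges))
}

#' Threshold a score matrix at a fixed cut-off
#'
#' An edge is drawn wherever the absolute score strictly exceeds the
#' cut-off (used e.g. for condition-specific stress networks at 0.82).
#'
#' @param S Symmetric score matrix with gene dimnames.
#' @param cutoff Non-negative score cut-off.
#' @return Binary symmetric adjacency matrix with attribute `cutoff`.
#' @export
threshold_fixed <- function(S, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop("cutoff must be a non-negative number")
  A <- (abs(unclass(S)) > cutoff) * 1L
  diag(A) <- 0L
  dimnames(A) <- dimnames(S)
  structure(A, cutoff = cutoff)
}

score_matrix_for <- function(x, method, power = 5) {
  switch(method,
         pearson = pearson_matrix(x),
         partial = partial_matrix(x),
         bicor   = bicor_matrix(x),
         `bicor-tom` = tom_similarity(bicor_matrix(x), power = power),
         stop("unknown method: ", method))
}

#' Bootstrap-aggregated adjacency matrix
#'
#' Resamples the samples (columns) with replacement `B` times; each
#' resample yields a sparsity-controlled network via
#' [threshold_to_sparsity()], and per-pair edge counts are aggregated
#' into a matrix with values in 0..B.  The final network keeps the pairs
#' whose count reaches the cut-off beta, chosen as the smallest integer
#' for which the realized sparsity does not exceed `omega` (the
#' conservative direction).  One master seed spawns a per-replicate
#' sub-seed stream, so enlarging `B` never reshuffles earlier replicates.
#'
#' @param x Numeric genes x samples matrix.
#' @param omega Target sparsity per replicate and for the final network.
#' @param B Number of bootstrap repetitions (50 in the reference
#'   workflow).
#' @param seed Integer master seed; fully determines the output.
#' @param method One of `"pearson"`, `"partial"`, `"bicor"`.
#' @param power Soft power, used only by TOM-based methods.
#' @return Binary adjacency matrix with attributes `counts` (the
#'   aggregated 0..B count matrix), `beta`, `omega`, `B`.
#' @export
bootstrap_adjacency <- function(x, omega, B = 50, seed = 1,
                                method = c("pearson", "partial", "bicor"),
                                power = 5) {
  method <- match.arg(method)
  if (B < 1) stop("B must be >= 1")
  validate_expression_matrix(x)
  n <- nrow(x); m <- ncol(x)
  M <- n * (n - 1) / 2
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, B)
  counts <- matrix(0L, n, n, dimnames = list(rownames(x), rownames(x)))
  for (b in seq_len(B)) {
    set.seed(sub_seeds[b])
    cols <- sample.int(m, m, replace = TRUE)
    xb <- x[, cols, drop = FALSE]
    colnames(xb) <- make.unique(colnames(x)[cols])
    S <- suppressWarnings(score_matrix_for(xb, method))
    Ab <- threshold_to_sparsity(S, omega)
    counts <- counts + unclass(Ab)
  }
  # smallest beta with realized sparsity <= omega
  target <- floor(omega * M + 1e-9)
  edge_counts <- counts[upper.tri(counts)]
  beta <- B + 1L
  for (bta in seq_len(B)) {
    if (sum(edge_counts >= bta) <= target) { beta <- bta; break }
  }
  A <- (counts >= beta) * 1L
  diag(A) <- 0L
  structure(A, counts = counts, beta = beta, omega = omega, B = B,
            method = method)
}

#' Intersect condition-specific networks
#'
#' Keeps only the edges present in every input network (aggregated score
#' equal to the number of networks), e.g. the common core of four
#' stress-specific networks.
#'
#' @param networks List of >= 2 binary adjacency matrices with identical
#'   gene order.
#' @return Binary adjacency matrix.
#' @export
intersect_condition_networks <- function(networks) {
  if (!is.list(networks) || length(networks) < 2L)
    stop("need a list of at least 2 networks")
  genes <- rownames(networks[[1L]])
  for (A in networks) {
    validate_adjacency(unclass_adj(A))
    if (!identical(rownames(A), genes))
      stop("gene order mismatch between networks")
  }
  total <- Reduce(`+`, lapply(networks, unclass_adj))
  out <- (total == length(networks)) * 1L
  dimnames(out) <- list(genes, genes)
  out
}

unclass_adj <- function(A) {
  A <- unclass(A)
  attributes(A) <- attributes(A)[c("dim", "dimnames")]
  A
}

#' Summarize a binary network
#' @param A Binary adjacency matrix or `coexnet` object.
#' @return List with `n_genes`, `n_edges`, `sparsity` (realized),
#'   `degree` (named integer vector), `n_nonisolated`.
#' @export
network_summary <- function(A) {
  if (inherits(A, "coexnet")) A <- A$adjacency
  validate_adjacency(unclass_adj(A))
  n <- nrow(A)
  deg <- as.integer(rowSums(A != 0))
  names(deg) <- rownames(A)
  n_edges <- sum(A[upper.tri(A)] != 0)
  list(n_genes = n,
       n_edges = as.integer(n_edges),
       sparsity = if (n > 1) n_edges / (n * (n - 1) / 2) else NA_real_,
       degree = deg,
       n_nonisolated = sum(deg > 0))
}
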