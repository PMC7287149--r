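# Statistical evaluation of sparsity-controlled networks.
#
# All networks compared here share the same sparsity omega, so the edge
# count inside any sub-network of n_A genes has a simple null: under a
# random network, K ~ Bin(C(n_A, 2), omega).  A sub-network is
# "pronounced" when its observed edge count exceeds the null expectation
# omega * C(n_A, 2).

resolve_adjacency <- function(A) {
  if (inherits(A, "coexnet")) A <- A$adjacency
  A
}

#' Count edges within a gene set
#' @param A Adjacency matrix or `coexnet`.
#' @param genes Character vector; members absent from the network are
#'   dropped with a warning.
#' @return List with `K` (observed edges, both endpoints in the set),
#'   `M` (possible edges C(n_A, 2)) and `n` (retained set size).
#' @export
count_edges_within <- function(A, genes) {
  A <- resolve_adjacency(A)
  keep <- intersect(genes, rownames(A))
  if (length(keep) < length(unique(genes)))
    warning(length(unique(genes)) - length(keep),
            " gene(s) not in network dropped")
  if (length(keep) < 2L)
    stop("fewer than 2 set members present in the network")
  sub <- A[keep, keep, drop = FALSE]
  list(K = as.integer(sum(sub[upper.tri(sub)] != 0)),
       M = choose(length(keep), 2),
       n = length(keep))
}

#' Count edges between two disjoint gene sets
#' @param A Adjacency matrix or `coexnet`.
#' @param set1,set2 Character vectors; genes occurring in both sets are
#'   removed from both (logged via warning) so the bipartite null is
#'   well defined.
#' @return List with `K` (edges with one endpoint in each set),
#'   `M = n1 * n2`, `n1`, `n2`.
#' @export
count_edges_between <- function(A, set1, set2) {
  A <- resolve_adjacency(A)
  s1 <- intersect(set1, rownames(A))
  s2 <- intersect(set2, rownames(A))
  both <- intersect(s1, s2)
  if (length(both)) {
    warning("gene(s) in both sets removed from both: ",
            paste(both, collapse = ", "))
    s1 <- setdiff(s1, both)
    s2 <- setdiff(s2, both)
  }
  if (!length(s1) || !length(s2))
    stop("both sets must retain at least one network gene")
  list(K = as.integer(sum(A[s1, s2, drop = FALSE] != 0)),
       M = length(s1) * length(s2),
       n1 = length(s1), n2 = length(s2))
}

#' Exact binomial test for a pronounced sub-network
#'
#' Under the null of a random network at sparsity `omega`, the edge count
#' within a sub-network with `M` possible edges is Bin(M, omega).  The
#' one-sided exact binomial tail gives the p-value; the sub-network is
#' flagged pronounced whenever K exceeds its null expectation
#' `omega * M`.
#'
#' @param K Observed edge count.
#' @param M Possible edge count.
#' @param omega Network sparsity.
#' @param alternative `"greater"` (enrichment, default) or `"less"`.
#' @return List of class `subnetwork_test`: `K`, `M`, `expected`
#'   (`omega * M`), `p_value`, `pronounced`.
#' @export
pronounced_test <- function(K, M, omega,
                            alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (K < 0 || K > M) stop("need 0 <= K <= M")
  if (omega <= 0 || omega >= 1) stop("omega must lie in (0, 1)")
  p <- stats::binom.test(K, M, p = omega,
                         alternative = alternative)$p.value
  structure(list(K = as.integer(K), M = M, omega = omega,
                 expected = omega * M, p_value = p,
                 pronounced = K > omega * M,
                 alternative = alternative),
            class = "subnetwork_test")
}

#' @export
print.subnetwork_test <- function(x, ...) {
  cat(sprintf("sub-network edges: K = %d of M = %g possible (expected %.3g at omega = %g)\n",
              x$K, x$M, x$expected, x$omega))
  cat(sprintf("  one-sided (%s) exact binomial p = %.3g; pronounced: %s\n",
              x$alternative, x$p_value, x$pronounced))
  invisible(x)
}

#' Compare edge counts of two networks by Fisher's exact test
#'
#' Two-sided Fisher test on the 2x2 table
#' rbind(c(K_A, M - K_A), c(K_B, M - K_B)) -- the null being that the two
#' networks (built at the same sparsity) have the same expected edge
#' count inside the sub-network.
#'
#' @param K_A,K_B Edge counts of the same sub-network in networks A and B.
#' @param M Possible edge count of the sub-network.
#' @return Two-sided p-value.
#' @export
compare_networks_fisher <- function(K_A, K_B, M) {
  if (K_A > M || K_B > M || K_A < 0 || K_B < 0)
    stop("need 0 <= K <= M")
  tab <- rbind(c(K_A, M - K_A), c(K_B, M - K_B))
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Compare non-isolated node counts of two networks
#'
#' Fisher's exact two-sided test of the null that the number of nodes
#' with at least one edge is the same in two networks over the same n
#' genes.
#'
#' @param nonisolated_A,nonisolated_B Non-isolated node counts.
#' @param n Total gene count.
#' @return Two-sided p-value.
#' @export
compare_node_counts_fisher <- function(nonisolated_A, n, nonisolated_B) {
  if (nonisolated_A > n || nonisolated_B > n)
    stop("counts cannot exceed n")
  tab <- rbind(c(nonisolated_A, n - nonisolated_A),
               c(nonisolated_B, n - nonisolated_B))
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Two-proportion z test
#'
#' Pooled-variance z statistic for comparing proportions k1/n1 and k2/n2:
#' z = (p1 - p2) / sqrt(pi * (1 - pi) * (1/n1 + 1/n2)) with pooled
#' pi = (k1 + k2) / (n1 + n2); two-sided p from the standard normal.
#'
#' @param k1,n1,k2,n2 Successes and trials of the two groups.
#' @return List of class `proportion_test`: `k1`, `n1`, `k2`, `n2`,
#'   `pi_pooled`, `z`, `p_value`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("n1 and n2 must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("need 0 <= k <= n in both groups")
  pi_hat <- (k1 + k2) / (n1 + n2)
  if (pi_hat == 0 || pi_hat == 1) {
    warning("pooled proportion is ", pi_hat, ": z undefined, p = 1")
    z <- NA_real_; p <- 1
  } else {
    se <- sqrt(pi_hat * (1 - pi_hat) * (1 / n1 + 1 / n2))
    z <- (k1 / n1 - k2 / n2) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 pi_pooled = pi_hat, z = z, p_value = p),
            class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf("two-proportion z: %d/%d vs %d/%d (pooled %.3g)\n",
              x$k1, x$n1, x$k2, x$n2, x$pi_pooled))
  cat(sprintf("  z = %.3g, two-sided p = %.3g\n", x$z, x$p_value))
  invisible(x)
}

#' Test a single gene's connectivity to a functional category
#'
#' Counts the edges from `gene` into `category` (the gene itself is
#' removed from the category first).  Under the default unconditional
#' null each of the m possible edges is present with probability omega,
#' so K ~ Bin(m, omega), tested one-sided.  With
#' `conditional = TRUE` the test conditions on the gene's realized
#' degree d: the neighbours are then an unordered sample of d of the
#' n - 1 other genes, giving a hypergeometric null.
#'
#' @param gene Gene id present in the network.
#' @param category Character vector of category member genes.
#' @param A Adjacency matrix or `coexnet`.
#' @param omega Network sparsity (unconditional null only).
#' @param alternative `"greater"` or `"less"`.
#' @param conditional Use the degree-conditioned hypergeometric null.
#' @return `subnetwork_test` list (with `M` = m, the category size).
#' @export
gene_category_test <- function(gene, category, A, omega,
                               alternative = c("greater", "less"),
                               conditional = FALSE) {
  alternative <- match.arg(alternative)
  A <- resolve_adjacency(A)
  if (!gene %in% rownames(A)) stop("gene not in network: ", gene)
  cat_genes <- intersect(setdiff(category, gene), rownames(A))
  m <- length(cat_genes)
  if (m < 1L) stop("category has no network members besides the gene")
  K <- as.integer(sum(A[gene, cat_genes] != 0))
  if (conditional) {
    d <- sum(A[gene, ] != 0)
    n_other <- nrow(A) - 1L
    p <- if (alternative == "greater")
      stats::phyper(K - 1, m, n_other - m, d, lower.tail = FALSE)
    else stats::phyper(K, m, n_other - m, d)
    structure(list(K = K, M = m, omega = NA_real_,
                   expected = d * m / n_other, p_value = p,
                   pronounced = K > d * m / n_other,
                   alternative = alternative),
              class = "subnetwork_test")
  } else {
    pronounced_test(K, m, omega, alternative)
  }
}

#' Guilt-by-association functional profile of one gene
#'
#' Breaks the annotated functions of a gene's network neighbours down by
#' category and asks, per category, whether the neighbour proportion
#' departs from the category's share of the annotated universe, via
#' [two_proportion_z()] with n1 = the gene's degree and n2 = the universe
#' size.  Over-represented categories among the neighbours of an
#' unannotated gene suggest its function.
#'
#' @param gene Gene id with at least one edge.
#' @param A Adjacency matrix or `coexnet`.
#' @param annotations Named character vector gene -> category (see
#'   [read_annotations()]).
#' @return Data frame with one row per category present among the
#'   annotated universe: `category`, `neighbors` (k1), `degree` (n1),
#'   `universe_in_category` (k2), `universe` (n2), `neighbor_prop`,
#'   `background_prop`, `z`, `p_value`; sorted by p-value.
#' @export
guilt_by_association_profile <- function(gene, A, annotations) {
  A <- resolve_adjacency(A)
  if (!gene %in% rownames(A)) stop("gene not in network: ", gene)
  neighbors <- rownames(A)[A[gene, ] != 0]
  if (!length(neighbors)) stop("gene has no edges: ", gene)
  universe <- names(annotations)
  n2 <- length(universe)
  ann_nb <- annotations[intersect(neighbors, universe)]
  n1 <- length(neighbors)
  cats <- sort(unique(annotations))
  rows <- lapply(cats, function(cg) {
    k1 <- sum(ann_nb == cg)
    k2 <- sum(annotations == cg)
    zt <- suppressWarnings(two_proportion_z(k1, n1, k2, n2))
    data.frame(category = cg, neighbors = k1, degree = n1,
               universe_in_category = k2, universe = n2,
               neighbor_prop = k1 / n1, background_prop = k2 / n2,
               z = ifelse(is.na(zt$z), 0, zt$z), p_value = zt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$category), , drop = FALSE]
}

#' Evaluate a whole gene-set catalog against a network
#'
#' Runs the pronounced-sub-network binomial test within every catalog set
#' and between every unordered pair of sets (on the bipartite possible
#' edges, shared genes removed), with Benjamini-Hochberg adjustment
#' applied separately to the within-set and between-set families.
#'
#' @param A Adjacency matrix or `coexnet`.
#' @param catalog Named list of gene sets.
#' @param omega Network sparsity.
#' @param between Also test every unordered pair of sets.
#' @return Data frame with columns `set` (or `set1`/`set2` combined as
#'   "a|b"), `type` (within/between), `n`, `M`, `K`, `expected`,
#'   `p_value`, `q_value`, `pronounced`.  Sets with fewer than 2 network
#'   genes are skipped with a warning.
#' @export
evaluate_catalog <- function(A, catalog, omega, between = TRUE) {
  A <- resolve_adjacency(A)
  if (!length(catalog)) stop("catalog is empty")
  usable <- vapply(catalog,
                   function(g) length(intersect(g, rownames(A))) >= 2L,
                   logical(1))
  if (any(!usable))
    warning("set(s) with < 2 network genes skipped: ",
            paste(names(catalog)[!usable], collapse = ", "))
  catalog <- catalog[usable]
  within_rows <- lapply(names(catalog), function(nm) {
    cw <- suppressWarnings(count_edges_within(A, catalog[[nm]]))
    tt <- pronounced_test(cw$K, cw$M, omega)
    data.frame(set = nm, type = "within", n = cw$n, M = cw$M, K = cw$K,
               expected = tt$expected, p_value = tt$p_value,
               pronounced = tt$pronounced, stringsAsFactors = FALSE)
  })
  within <- do.call(rbind, within_rows)
  within$q_value <- stats::p.adjust(within$p_value, method = "BH")
  out <- within
  if (between && length(catalog) >= 2L) {
    pairs <- utils::combn(names(catalog), 2, simplify = FALSE)
    between_rows <- lapply(pairs, function(pr) {
      cb <- suppressWarnings(count_edges_between(A, catalog[[pr[1]]],
                                                 catalog[[pr[2]]]))
      tt <- pronounced_test(cb$K, cb$M, omega)
      data.frame(set = paste(pr, collapse = "|"), type = "between",
                 n = cb$n1 + cb$n2, M = cb$M, K = cb$K,
                 expected = tt$expected, p_value = tt$p_value,
                 pronounced = tt$pronounced, stringsAsFactors = FALSE)
    })
    btw <- do.call(rbind, between_rows)
    btw$q_value <- stats::p.adjust(btw$p_value, method = "BH")
    out <- rbind(within, btw)
  }
  rownames(out) <- NULL
  out[, c("set", "type", "n", "M", "K", "expected",
          "p_value", "q_value", "pronounced")]
}
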