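# Reference communities by random-walk clustering, and their overlay onto
# condition-specific networks.

#' Walktrap community detection on a binary network
#'
#' Pons-Latapy agglomerative clustering: short random walks of length
#' `steps` define a node distance, communities are merged bottom-up and
#' the dendrogram is cut where modularity is maximal.  Isolated nodes are
#' excluded from clustering and reported separately ("unassigned").
#'
#' @param A Binary adjacency matrix or `coexnet`.
#' @param steps Random-walk length (default 4, the algorithm's standard
#'   setting).
#' @return List of class `community_partition`: `membership` (named
#'   integer vector over non-isolated genes, community ids 1..c),
#'   `n_communities`, `steps`, `modularity`, `unassigned` (isolated gene
#'   ids).
#' @export
walktrap_communities <- function(A, steps = 4) {
  A <- resolve_adjacency(A)
  validate_adjacency(unclass_adj(A))
  deg <- rowSums(A != 0)
  if (all(deg == 0)) stop("network has no edges")
  keep <- deg > 0
  g <- igraph::graph_from_adjacency_matrix(A[keep, keep] != 0,
                                           mode = "undirected")
  wt <- igraph::cluster_walktrap(g, steps = steps)
  memb <- igraph::membership(wt)
  out <- list(membership = stats::setNames(as.integer(memb),
                                           rownames(A)[keep]),
              n_communities = length(unique(memb)),
              steps = steps,
              modularity = igraph::modularity(g, memb),
              unassigned = rownames(A)[!keep])
  class(out) <- "community_partition"
  out
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities over %d genes (walk length %d)\n",
              x$n_communities, length(x$membership), x$steps))
  cat(sprintf("  modularity %.4g; %d isolated genes unassigned\n",
              x$modularity, length(x$unassigned)))
  print(table(community = x$membership))
  invisible(x)
}

#' Overlay a reference community partition onto a stress network
#'
#' Cross-references a condition-specific (e.g. stress) network with a
#' reference community partition built on centralized data: each stress
#' node is labelled with its reference community (or "unassigned"), its
#' degree in the stress network, and optionally a membership flag for a
#' user-supplied shared-gene set (e.g. genes common to root and shoot
#' stress networks).
#'
#' @param stress_net Adjacency matrix or `coexnet`.
#' @param partition A `community_partition`.
#' @param shared_genes Optional character vector to flag.
#' @return List with `nodes` (data frame: gene, community, degree,
#'   shared) and `occupancy` (data frame: community, n_nodes -- counts of
#'   stress-network non-isolated nodes per reference community).
#' @export
overlay_communities <- function(stress_net, partition,
                                shared_genes = NULL) {
  A <- resolve_adjacency(stress_net)
  genes <- rownames(A)
  if (!length(intersect(genes, names(partition$membership))))
    stop("stress network and reference partition share no genes")
  comm <- partition$membership[genes]
  lab <- ifelse(is.na(comm), "unassigned", as.character(comm))
  deg <- as.integer(rowSums(A != 0))
  nodes <- data.frame(gene = genes, community = lab, degree = deg,
                      stringsAsFactors = FALSE)
  if (!is.null(shared_genes))
    nodes$shared <- genes %in% shared_genes
  occ <- table(nodes$community[nodes$degree > 0])
  occupancy <- data.frame(community = names(occ),
                          n_nodes = as.integer(occ),
                          stringsAsFactors = FALSE)
  list(nodes = nodes, occupancy = occupancy)
}

#' Per-community enrichment of a stress-responsive gene set
#'
#' For every reference community, compares its share of stress genes with
#' the background share in the full universe via [two_proportion_z()].
#'
#' @param partition A `community_partition`.
#' @param stress_genes Character vector, subset of `universe`.
#' @param universe Character vector of all genes under consideration.
#' @return Data frame with one row per non-empty community: `community`,
#'   `n` (community size), `stress_in_community`, `z`, `p_value`, sorted
#'   by p-value.
#' @export
community_stress_enrichment <- function(partition, stress_genes,
                                        universe) {
  if (!length(stress_genes)) stop("stress gene set is empty")
  extra <- setdiff(stress_genes, universe)
  if (length(extra))
    stop("stress gene(s) outside the universe: ",
         paste(extra, collapse = ", "))
  k2 <- length(intersect(stress_genes, universe))
  n2 <- length(universe)
  comms <- sort(unique(partition$membership))
  rows <- lapply(comms, function(cm) {
    members <- names(partition$membership)[partition$membership == cm]
    members <- intersect(members, universe)
    n1 <- length(members)
    if (!n1) return(NULL)
    k1 <- length(intersect(members, stress_genes))
    zt <- suppressWarnings(two_proportion_z(k1, n1, k2, n2))
    data.frame(community = cm, n = n1, stress_in_community = k1,
               z = ifelse(is.na(zt$z), 0, zt$z), p_value = zt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$community), , drop = FALSE]
}
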