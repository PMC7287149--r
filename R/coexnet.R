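#' Fit a gene co-expression network
#'
#' One-stop constructor for the network estimators in this package.  The
#' pipeline is: optional centralization within sub-experiments
#' ([cse()]), pairwise association by the chosen estimator, then
#' binarization -- either at a controlled sparsity `omega` (default), at
#' a fixed score `cutoff`, or by bootstrap aggregation when
#' `bootstrap > 0`.
#'
#' @param x Numeric genes x samples expression matrix.
#' @param design Optional `experiment_design`; required when
#'   `centralize = TRUE`.
#' @param method Association estimator: `"pearson"`, `"partial"`,
#'   `"bicor"` or `"bicor-tom"` (biweight midcorrelation followed by
#'   topological overlap).
#' @param omega Target sparsity (fraction of possible edges), default
#'   0.005.
#' @param centralize Apply CSE before correlating (needs `design`).
#' @param power Soft-thresholding power for TOM-based methods.
#' @param bootstrap Number of bootstrap repetitions; 0 disables
#'   bootstrapping.
#' @param cutoff If non-`NULL`, binarize at this fixed absolute-score
#'   cut-off instead of controlling sparsity.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `coexnet`: a list with elements
#'   `adjacency` (binary matrix), `scores` (the score matrix, `NULL` for
#'   bootstrap fits), `gene_ids`, `method`, `omega`, `alpha`/`beta`
#'   thresholds, `centralized`, and `call`.
#' @examples
#' sim <- generate_dataset(generator_config(n_genes = 40,
#'   module_sizes = rep(10, 2), s = 10, r = 3, n_confounded = 0))
#' net <- coexpression_network(sim$expression, sim$design,
#'                             method = "pearson", omega = 0.02,
#'                             centralize = TRUE)
#' print(net)
#' @export
coexpression_network <- function(x, design = NULL,
                                 method = c("pearson", "partial",
                                            "bicor", "bicor-tom"),
                                 omega = 0.005, centralize = FALSE,
                                 power = 5, bootstrap = 0,
                                 cutoff = NULL, seed = 1) {
  method <- match.arg(method)
  cl <- match.call()
  validate_expression_matrix(x)
  if (centralize) {
    if (is.null(design))
      stop("centralize = TRUE requires a design")
    x <- cse(x, design)
  }
  if (bootstrap > 0) {
    if (method == "bicor-tom")
      stop("bootstrap aggregation supports pearson, partial and bicor")
    A <- bootstrap_adjacency(x, omega = omega, B = bootstrap,
                             seed = seed, method = method, power = power)
    obj <- list(adjacency = unclass_adj(A), scores = NULL,
                counts = attr(A, "counts"),
                gene_ids = rownames(x), method = method, omega = omega,
                alpha = NA_real_, beta = attr(A, "beta"),
                bootstrap = bootstrap, centralized = centralize,
                call = cl)
  } else {
    S <- score_matrix_for(x, method, power = power)
    A <- if (is.null(cutoff)) threshold_to_sparsity(S, omega)
         else threshold_fixed(S, cutoff)
    obj <- list(adjacency = unclass_adj(A), scores = unclass(S),
                counts = NULL,
                gene_ids = rownames(x), method = method,
                omega = if (is.null(cutoff)) omega else NA_real_,
                alpha = if (is.null(cutoff)) attr(A, "alpha") else cutoff,
                beta = NA_integer_, bootstrap = 0,
                centralized = centralize, call = cl)
  }
  class(obj) <- "coexnet"
  obj
}

#' @export
print.coexnet <- function(x, ...) {
  s <- network_summary(x$adjacency)
  cat("Gene co-expression network (", x$method,
      if (x$centralized) ", CSE" else ", non-CSE", ")\n", sep = "")
  cat(sprintf("  %d genes, %d edges (sparsity %.4g)\n",
              s$n_genes, s$n_edges, s$sparsity))
  if (x$bootstrap > 0)
    cat(sprintf("  bootstrap B = %d, count cut-off beta = %d\n",
                x$bootstrap, x$beta))
  else if (!is.na(x$alpha))
    cat(sprintf("  absolute-score cut-off alpha = %.4g\n", x$alpha))
  cat(sprintf("  %d of %d genes non-isolated\n",
              s$n_nonisolated, s$n_genes))
  invisible(x)
}

#' @export
summary.coexnet <- function(object, ...) {
  s <- network_summary(object$adjacency)
  s$method <- object$method
  s$centralized <- object$centralized
  class(s) <- "summary.coexnet"
  s
}

#' @export
print.summary.coexnet <- function(x, ...) {
  cat(sprintf("coexnet summary: %d genes, %d edges, sparsity %.4g, %d non-isolated\n",
              x$n_genes, x$n_edges, x$sparsity, x$n_nonisolated))
  cat("degree distribution:\n")
  print(summary(x$degree))
  invisible(x)
}

#' Convert a coexnet to an igraph graph
#' @param x A `coexnet` object.
#' @param ... Unused.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @export
as_igraph.coexnet <- function(x, ...)
  igraph::graph_from_adjacency_matrix(x$adjacency != 0,
                                      mode = "undirected")

#' @export
as.matrix.coexnet <- function(x, ...) x$adjacency

#' @export
plot.coexnet <- function(x, vertex.size = 4, vertex.label = NA, ...) {
  g <- as_igraph(x)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  plot(g, vertex.size = vertex.size, vertex.label = vertex.label, ...)
  invisible(x)
}
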