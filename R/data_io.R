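#' Read a gene expression matrix from a tab-separated file
#'
#' The file must carry gene identifiers in the first column, sample
#' identifiers in the header row, and a complete numeric body.  Values are
#' assumed to be normalized, log-scale expression; the package never
#' log-transforms silently.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) with unique `rownames`
#'   (genes) and `colnames` (samples), in file order.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("expression file needs a gene-id column plus at least one sample")
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  # locate bad cells before coercion so errors can carry coordinates
  bad <- which(is.na(body) | body == "" |
                 is.na(suppressWarnings(as.numeric(body))), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("missing or non-numeric value at gene '%s', sample '%s' (row %d, column %d)",
                 gene_ids[i], sample_ids[j], i, j))
  }
  x <- matrix(as.numeric(body), nrow = nrow(body),
              dimnames = list(gene_ids, sample_ids))
  validate_expression_matrix(x)
  x
}

#' Write an expression matrix as TSV (inverse of [read_expression_matrix()])
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicated gene ids")
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample ids")
  if (anyNA(x))
    stop("expression matrix contains missing values")
  invisible(x)
}

#' Read a sample design table mapping samples to sub-experiments
#'
#' A sub-experiment is a group of assays produced under identical
#' experimental settings, i.e. biological replicates.  The design drives
#' the centralization step ([cse()]).
#'
#' @param path TSV file with header columns `sample_id`, `sub_experiment`
#'   and optionally `tissue` and `treatment`.
#' @return A `data.frame` of class `experiment_design`; attributes
#'   `n_subexperiments` and `replicates` report s and the multiset of
#'   group sizes r_j.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = TRUE)
  req <- c("sample_id", "sub_experiment")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("design file lacks column(s): ", paste(miss, collapse = ", "))
  as_experiment_design(df)
}

#' Construct/validate an experiment design
#' @param df Data frame with `sample_id`, `sub_experiment`, optional
#'   `tissue`, `treatment` columns.
#' @export
as_experiment_design <- function(df) {
  df$sample_id <- as.character(df$sample_id)
  df$sub_experiment <- as.character(df$sub_experiment)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("sample(s) listed more than once in design: ",
         paste(dup, collapse = ", "))
  r <- table(df$sub_experiment)
  if (any(r == 1L))
    warning("sub-experiment(s) with a single sample: ",
            paste(names(r)[r == 1L], collapse = ", "),
            " (their centralized values will be exactly 0)")
  attr(df, "n_subexperiments") <- length(r)
  attr(df, "replicates") <- as.integer(r)
  class(df) <- c("experiment_design", "data.frame")
  df
}

# Pair a design with an expression matrix; errors list unmatched samples.
match_design <- function(x, design) {
  samples <- colnames(x)
  missing_in_design <- setdiff(samples, design$sample_id)
  if (length(missing_in_design))
    stop("sample(s) in expression matrix but not in design: ",
         paste(missing_in_design, collapse = ", "))
  design[match(samples, design$sample_id), , drop = FALSE]
}

#' Quantile-normalize the columns of an expression matrix
#'
#' Forces every sample (column) onto the identical reference distribution:
#' the across-sample mean of order statistics.  Within-column ranks are
#' preserved; ties receive the mean of the reference values at their tied
#' rank positions (rank-average dialect).  Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x Numeric genes x samples matrix, complete, with >= 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L)
    stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Read gene sets from a GMT file
#' @param path GMT file (set name, description, member genes per line).
#' @return Named list of character vectors (a gene-set catalog).
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicated gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column gene -> functional-category annotation table
#' @param path TSV with columns `gene` and `category` (header required).
#' @return Named character vector: names are genes, values categories.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation file needs two columns")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicated gene(s) in annotation table: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  stats::setNames(as.character(df[[2L]]), genes)
}

#' Export a network as an edge list or GraphML
#'
#' Edge lists are written with columns `gene_a`, `gene_b`, `score`, one row
#' per edge, with each unordered pair canonicalized so that
#' `gene_a < gene_b` lexicographically (diff-stable output).  GraphML
#' export goes through igraph and can carry per-node `community` and
#' `dominance` attributes.
#'
#' @param adjacency Binary symmetric adjacency matrix with gene dimnames,
#'   or a `coexnet` object.
#' @param path Output file.
#' @param scores Optional symmetric score matrix in the same gene order;
#'   edge scores are left blank when absent.
#' @param format `"edgelist"` or `"graphml"`.
#' @param node_attrs Optional data frame of per-node attributes with a
#'   `gene` column (GraphML only).
#' @export
write_network <- function(adjacency, path, scores = NULL,
                          format = c("edgelist", "graphml"),
                          node_attrs = NULL) {
  format <- match.arg(format)
  if (inherits(adjacency, "coexnet")) {
    if (is.null(scores)) scores <- adjacency$scores
    adjacency <- adjacency$adjacency
  }
  validate_adjacency(adjacency)
  genes <- rownames(adjacency)
  if (!is.null(scores) && !identical(rownames(scores), genes))
    stop("score matrix gene order differs from adjacency")
  idx <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
  a <- genes[idx[, 1L]]; b <- genes[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b)
  edges <- data.frame(gene_a = a[ord], gene_b = b[ord],
                      stringsAsFactors = FALSE)
  edges$score <- if (is.null(scores)) rep("", nrow(edges)) else
    scores[cbind(idx[ord, 1L], idx[ord, 2L])]
  if (format == "edgelist") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(adjacency != 0,
                                             mode = "undirected")
    if (!is.null(scores) && igraph::ecount(g) > 0) {
      el <- igraph::as_edgelist(g)
      igraph::E(g)$score <- scores[cbind(match(el[, 1], genes),
                                         match(el[, 2], genes))]
    }
    if (!is.null(node_attrs)) {
      for (col in setdiff(colnames(node_attrs), "gene")) {
        vals <- node_attrs[[col]][match(genes, node_attrs$gene)]
        g <- igraph::set_vertex_attr(g, col, value = as.character(vals))
      }
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge-list TSV back into an adjacency matrix
#' @param path Edge-list file written by [write_network()].
#' @param genes Character vector giving the full gene universe (isolated
#'   genes cannot be recovered from the edge list alone).
#' @return Binary symmetric adjacency matrix over `genes`.
#' @export
read_network <- function(path, genes) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  A <- matrix(0L, length(genes), length(genes),
              dimnames = list(genes, genes))
  if (nrow(df)) {
    ia <- match(df$gene_a, genes); ib <- match(df$gene_b, genes)
    if (anyNA(ia) || anyNA(ib))
      stop("edge list refers to genes outside the supplied universe")
    A[cbind(ia, ib)] <- 1L
    A[cbind(ib, ia)] <- 1L
  }
  A
}

validate_adjacency <- function(A) {
  if (!is.matrix(A)) stop("adjacency must be a matrix")
  if (is.null(rownames(A)) || !identical(rownames(A), colnames(A)))
    stop("adjacency must have identical gene rownames and colnames")
  if (any(A != 0 & A != 1)) stop("adjacency must be binary")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  invisible(A)
}
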