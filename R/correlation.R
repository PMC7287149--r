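# Gene-gene similarity estimators.  All return symmetric matrices with
# unit diagonal and the gene order of the input; the unsigned network
# convention (absolute scores) is applied downstream, at thresholding.

#' Pearson correlation matrix between genes
#'
#' Product-moment correlation across samples for every gene pair.  Genes
#' with zero variance cannot be correlated: their rows and columns are set
#' to 0 (diagonal 1) and their ids are returned in the `zero_variance`
#' attribute.
#'
#' @param x Numeric genes x samples matrix.
#' @return Symmetric correlation matrix with attribute `method = "pearson"`.
#' @export
pearson_matrix <- function(x) {
  validate_expression_matrix(x)
  v <- apply(x, 1L, stats::var)
  flat <- v == 0 | is.na(v)
  C <- suppressWarnings(stats::cor(t(x)))
  if (any(flat)) {
    C[flat, ] <- 0
    C[, flat] <- 0
    warning("zero-variance gene(s) set to 0 correlation: ",
            paste(rownames(x)[flat], collapse = ", "))
  }
  diag(C) <- 1
  structure(C, method = "pearson",
            zero_variance = rownames(x)[flat])
}

#' Full-order partial correlation matrix
#'
#' The partial correlation of each gene pair given all remaining genes,
#' computed from the (pseudo-)inverse Omega of the gene correlation
#' matrix: rho_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj).  This is the
#' Gaussian graphical model estimate of direct association.  When the
#' correlation matrix is singular (more genes than samples, or collinear
#' genes) the Moore-Penrose pseudo-inverse is used, with a warning;
#' singular values below 1e-10 of the largest are treated as zero.
#'
#' @param x Numeric genes x samples matrix with >= 2 genes.
#' @return Symmetric matrix with unit diagonal, attribute
#'   `method = "partial"`.
#' @export
partial_matrix <- function(x) {
  validate_expression_matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("partial correlation needs at least 2 genes")
  C <- pearson_matrix(x)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("singular correlation matrix (p >= n or collinearity): using Moore-Penrose pseudo-inverse")
    Om <- MASS::ginv(unclass(C), tol = 1e-10)
  } else {
    Om <- solve(unclass(C))
  }
  d <- sqrt(abs(diag(Om)))
  P <- -Om / tcrossprod(d)
  P <- (P + t(P)) / 2
  diag(P) <- 1
  P[P > 1] <- 1; P[P < -1] <- -1
  dimnames(P) <- dimnames(C)
  structure(P, method = "partial")
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation based on median/MAD standardization with Tukey
#' biweights (tuning constant 9): observations further than 9 MADs from
#' the median get zero weight, so single gross outliers barely move the
#' estimate.  Genes whose MAD is zero cannot be standardized; their pairs
#' fall back to Pearson correlation (ids reported in the `mad_zero`
#' attribute).
#'
#' @param x Numeric genes x samples matrix.
#' @return Symmetric correlation matrix, attribute `method = "bicor"`.
#' @export
bicor_matrix <- function(x) {
  validate_expression_matrix(x)
  n <- nrow(x)
  med <- apply(x, 1L, stats::median)
  madv <- apply(x, 1L, stats::mad, constant = 1)
  ok <- madv > 0
  xc <- x - med
  U <- xc / (9 * madv)           # rows with mad 0 give Inf; masked below
  W <- (1 - U^2)^2 * (abs(U) < 1)
  Z <- xc * W
  Z[!ok, ] <- 0
  nrm <- sqrt(rowSums(Z^2))
  nrm[nrm == 0] <- 1
  Z <- Z / nrm
  C <- tcrossprod(Z)
  if (any(!ok)) {
    warning("gene(s) with MAD = 0 fall back to Pearson: ",
            paste(rownames(x)[!ok], collapse = ", "))
    P <- suppressWarnings(pearson_matrix(x))   # MAD-0 warning already covers these genes
    C[!ok, ] <- P[!ok, ]
    C[, !ok] <- P[, !ok]
  }
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(rownames(x), rownames(x))
  structure(C, method = "bicor", mad_zero = rownames(x)[!ok])
}

#' Topological overlap matrix (TOM) similarity
#'
#' Converts a correlation-type matrix into an unsigned soft adjacency
#' a_ij = |c_ij|^power and measures, for every pair, how much of the
#' network neighbourhood the two genes share:
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), where
#' l_ij = sum_u a_iu a_uj over u != i, j and k_i is the soft connectivity
#' of gene i.  Values lie in [0, 1]; the diagonal is 1.
#'
#' @param C Correlation-type matrix (entries in [-1, 1], unit diagonal).
#' @param power Positive soft-thresholding exponent.  No automatic
#'   scale-free fit is performed; supply the power appropriate to the
#'   analysis (5 is the conventional whole-data default here).
#' @return Symmetric TOM matrix, attribute `method = "tom"`.
#' @export
tom_similarity <- function(C, power = 5) {
  if (!is.numeric(power) || length(power) != 1L || power <= 0)
    stop("power must be a positive number")
  if (max(abs(C)) > 1 + 1e-8)
    stop("input must be a correlation-type matrix (entries in [-1, 1])")
  A <- abs(unclass(C))^power
  diag(A) <- 0
  L <- A %*% A                   # l_ij: u = i and u = j terms vanish
  k <- rowSums(A)
  mink <- outer(k, k, pmin)
  TOM <- (L + A) / (mink + 1 - A)
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(C)
  structure(TOM, method = "tom", power = power)
}

#' Consensus TOM across condition-specific networks
#'
#' Element-wise minimum of TOM matrices built on data subsets (e.g. one
#' per tissue): a pair scores highly only if it scores highly in every
#' subset.
#'
#' @param toms List of >= 2 score matrices with identical gene order.
#' @return Matrix of element-wise minima.
#' @export
consensus_tom <- function(toms) {
  if (!is.list(toms) || length(toms) < 2L)
    stop("need a list of at least 2 matrices")
  genes <- rownames(toms[[1L]])
  for (m in toms[-1L])
    if (!identical(rownames(m), genes))
      stop("gene order mismatch between consensus inputs")
  out <- Reduce(pmin, lapply(toms, unclass))
  dimnames(out) <- dimnames(toms[[1L]])
  structure(out, method = "consensus_tom")
}
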