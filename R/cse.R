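#' Centralization within sub-experiments (CSE)
#'
#' Mean-centers each gene separately within each sub-experiment, i.e.
#' subtracts from every value the mean expression of that gene across the
#' biological replicates of its sub-experiment.  The centralized data have
#' exactly zero mean within every (gene, sub-experiment) cell, which
#' removes all between-condition mean differences -- treatment, tissue and
#' batch effects alike -- before any correlation is estimated.  What
#' survives is the replicate-level covariation that is shared across
#' sub-experiments: the "core" co-expression signal.
#'
#' Centering only: values are not rescaled, so genes keep their
#' replicate-level variance.  The operation is idempotent.
#'
#' @param x Numeric genes x samples matrix (see
#'   [read_expression_matrix()]).
#' @param design An `experiment_design` (see [read_design()]) covering
#'   every sample of `x`.
#' @param drop_singletons If `TRUE`, samples belonging to sub-experiments
#'   of size 1 are dropped instead of being zeroed; zeroed samples carry
#'   no information and dilute correlations.
#' @return A matrix of the same shape (fewer columns if
#'   `drop_singletons = TRUE`), same dimnames.
#' @examples
#' x <- rbind(g1 = c(3, 5, 7, 10, 10))
#' colnames(x) <- paste0("s", 1:5)
#' d <- as_experiment_design(data.frame(
#'   sample_id = paste0("s", 1:5),
#'   sub_experiment = c("A", "A", "A", "B", "B")))
#' cse(x, d)   # (-2, 0, 2, 0, 0)
#' @export
cse <- function(x, design, drop_singletons = FALSE) {
  validate_expression_matrix(x)
  d <- match_design(x, design)
  groups <- factor(d$sub_experiment, levels = unique(d$sub_experiment))
  sizes <- table(groups)
  if (any(sizes == 1L) && !drop_singletons)
    warning("sub-experiment(s) of size 1 (",
            paste(names(sizes)[sizes == 1L], collapse = ", "),
            "): their centralized values are exactly 0")
  out <- x
  for (g in levels(groups)) {
    cols <- which(groups == g)
    out[, cols] <- x[, cols, drop = FALSE] -
      rowMeans(x[, cols, drop = FALSE])
  }
  if (drop_singletons && any(sizes == 1L))
    out <- out[, groups %in% names(sizes)[sizes > 1L], drop = FALSE]
  out
}

#' Classify genes as below- or above-ground dominant
#'
#' For each gene the difference Delta_i between its mean expression in
#' below-ground samples (e.g. roots) and above-ground samples (e.g. shoots
#' and leaves) is computed on the raw (non-centralized) matrix; dominance
#' is defined by absolute tissue expression, which centralization would
#' erase.  Genes with Delta_i greater than one standard deviation of all
#' Delta values are below-ground dominant, those below minus one standard
#' deviation above-ground dominant, the rest neither.  The standard
#' deviation is the sample estimator (denominator n - 1) over all genes.
#'
#' @param x Numeric genes x samples matrix, non-centralized.
#' @param below_samples,above_samples Disjoint, non-empty character
#'   vectors of sample ids present in `x`.
#' @return A data frame of class `dominance_result` with columns `gene`,
#'   `delta`, `label` (factor: below/above/neither); attribute `s_delta`.
#' @export
classify_tissue_dominance <- function(x, below_samples, above_samples) {
  validate_expression_matrix(x)
  if (!length(below_samples) || !length(above_samples))
    stop("both sample groups must be non-empty")
  if (length(intersect(below_samples, above_samples)))
    stop("sample groups must be disjoint")
  miss <- setdiff(c(below_samples, above_samples), colnames(x))
  if (length(miss))
    stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))
  delta <- rowMeans(x[, below_samples, drop = FALSE]) -
    rowMeans(x[, above_samples, drop = FALSE])
  if (length(delta) < 2L)
    stop("at least 2 genes are needed to estimate s_delta (n - 1 > 0)")
  s_delta <- stats::sd(delta)
  if (s_delta == 0) {
    warning("all Delta values identical (s_delta = 0): labelling every gene 'neither'")
    label <- rep("neither", length(delta))
  } else {
    label <- ifelse(delta > s_delta, "below",
                    ifelse(delta < -s_delta, "above", "neither"))
  }
  res <- data.frame(gene = rownames(x), delta = unname(delta),
                    label = factor(label, levels = c("below", "above", "neither")),
                    stringsAsFactors = FALSE)
  attr(res, "s_delta") <- s_delta
  class(res) <- c("dominance_result", "data.frame")
  res
}
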