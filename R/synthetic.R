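# Synthetic expression data with known ground truth.
#
# Generating model, per gene i, sub-experiment j, replicate k:
#
#   x_ijk = mu_i + beta_i * delta_j + lambda * f_{m(i),jk} + eps_ijk
#
# where delta_j is a treatment effect fixed within sub-experiment j and
# shared by all treatment-responsive genes (beta_i != 0), f_{m,jk} is a
# standard-normal latent factor drawn independently per module per
# replicate (rank-1 within-module co-expression), and eps is
# N(0, sigma^2) noise.  The treatment term is constant across the
# replicates of a sub-experiment -- exactly the component that
# centralization within sub-experiments removes -- so responsive genes in
# unrelated modules are spuriously correlated before centralization and
# uncorrelated after it.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a compendium-like design: 300 genes, 10 co-expression
#' modules of 15 genes (the rest background), 40 sub-experiments of 3
#' replicates, 50 treatment-responsive genes spread over the whole gene
#' universe, treatment effects of standard deviation 3 against unit
#' loading and unit noise.
#'
#' @param n_genes Total number of genes.
#' @param module_sizes Integer vector partitioning a subset of the genes
#'   into co-expression modules.
#' @param lambda Within-module factor loading (shared by all module
#'   genes); the population within-module correlation is
#'   lambda^2 / (lambda^2 + sigma^2).
#' @param s Number of sub-experiments.
#' @param r Replicates per sub-experiment (the compendium emulated has 2
#'   or 3; a scalar or length-`s` vector).
#' @param n_confounded Number of treatment-responsive genes (beta_i = 1),
#'   sampled over the whole gene universe so responsive pairs span
#'   modules.
#' @param delta_sd Standard deviation of the per-sub-experiment treatment
#'   effects delta_j.
#' @param sigma Noise standard deviation (> 0).
#' @param mu Baseline mean expression, recycled over genes.
#' @param delta Optional fixed vector of length `s` of treatment effects;
#'   when `NULL`, delta_j ~ N(0, delta_sd^2) is drawn once per dataset.
#' @param seed Master seed; together with the config it fully determines
#'   the dataset.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_genes = 300, module_sizes = rep(15L, 10),
                             lambda = 1, s = 40, r = 3,
                             n_confounded = 50, delta_sd = 3,
                             sigma = 1, mu = 8, delta = NULL, seed = 1) {
  if (sum(module_sizes) > n_genes)
    stop("module sizes sum to more than n_genes")
  if (any(module_sizes < 2))
    stop("modules need at least 2 genes")
  r <- as.integer(rep_len(r, s))
  if (any(r < 2)) stop("replicates per sub-experiment must be >= 2")
  if (sigma <= 0) stop("sigma must be > 0")
  if (n_confounded > n_genes)
    stop("more responsive genes than genes")
  if (!is.null(delta) && length(delta) != s)
    stop("delta must have length s")
  structure(list(n_genes = n_genes, module_sizes = as.integer(module_sizes),
                 lambda = lambda, s = as.integer(s), r = r,
                 n_confounded = as.integer(n_confounded),
                 delta_sd = delta_sd, sigma = sigma, mu = mu,
                 delta = delta, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic expression dataset with known truth
#'
#' @param config A [generator_config()].
#' @return List with `expression` (genes x samples matrix), `design`
#'   (`experiment_design`; sub-experiments alternate "root"/"shoot"
#'   tissue labels), and `truth`, a list holding `module` (named integer
#'   vector, NA for background genes), `beta` (named numeric),
#'   `delta` (length-s vector used), `true_edges` (2-column matrix of
#'   same-module gene pairs) and `confounded_pairs` (2-column matrix of
#'   responsive pairs in different modules or background).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%03d", seq_len(n))
  module <- rep(NA_integer_, n)
  module[seq_len(sum(config$module_sizes))] <-
    rep(seq_along(config$module_sizes), config$module_sizes)
  names(module) <- genes
  beta <- stats::setNames(numeric(n), genes)
  responsive <- sort(sample.int(n, config$n_confounded))
  beta[responsive] <- 1
  delta <- if (is.null(config$delta))
    stats::rnorm(config$s, 0, config$delta_sd) else config$delta

  n_samples <- sum(config$r)
  subexp <- rep(seq_len(config$s), config$r)
  samples <- unlist(lapply(seq_len(config$s), function(j)
    sprintf("s%02d_r%d", j, seq_len(config$r[j]))))
  n_modules <- length(config$module_sizes)
  # latent factor per module per sample (independent across replicates)
  f <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
  eps <- matrix(stats::rnorm(n * n_samples, 0, config$sigma), n, n_samples)
  x <- matrix(rep_len(config$mu, n), n, n_samples) +
    outer(beta, delta[subexp]) + eps
  in_mod <- !is.na(module)
  x[in_mod, ] <- x[in_mod, ] + config$lambda * f[module[in_mod], ]
  dimnames(x) <- list(genes, samples)

  design <- as_experiment_design(data.frame(
    sample_id = samples,
    sub_experiment = sprintf("e%02d", subexp),
    tissue = c("root", "shoot")[(subexp %% 2L) + 1L],
    stringsAsFactors = FALSE))

  pairs <- function(keep) {
    idx <- which(keep, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    cbind(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]])
  }
  same_module <- outer(module, module, `==`) & !is.na(outer(module, module, `+`))
  both_resp <- outer(beta != 0, beta != 0, `&`)
  truth <- list(module = module, beta = beta, delta = delta,
                true_edges = pairs(same_module),
                confounded_pairs = pairs(both_resp & !same_module))
  list(expression = x, design = design, truth = truth)
}

#' Build gene-set and annotation fixtures from a synthetic truth
#'
#' One gene set per true module, plus one size-matched decoy set per
#' module drawn without replacement from the whole gene universe; and a
#' one-category-per-gene annotation table (module id, or "background").
#'
#' @param truth The `truth` element of [generate_dataset()] output.
#' @param seed Seed for the decoy draws.
#' @return List with `catalog` (named list of gene sets: `module_*` then
#'   `decoy_*`) and `annotations` (named character vector gene ->
#'   category).
#' @export
generate_annotations <- function(truth, seed = 1) {
  set.seed(as.integer(seed))
  genes <- names(truth$module)
  mods <- sort(unique(truth$module[!is.na(truth$module)]))
  catalog <- list()
  for (m in mods)
    catalog[[sprintf("module_%02d", m)]] <-
      genes[!is.na(truth$module) & truth$module == m]
  for (m in mods)
    catalog[[sprintf("decoy_%02d", m)]] <-
      sort(sample(genes, length(catalog[[sprintf("module_%02d", m)]])))
  annotations <- ifelse(is.na(truth$module), "background",
                        sprintf("module_%02d", truth$module))
  names(annotations) <- genes
  list(catalog = catalog, annotations = annotations)
}

#' Fraction of network edges connecting same-module genes
#'
#' Precision of a network against a synthetic truth: the proportion of
#' realized edges whose two endpoints lie in the same true module.
#'
#' @param A Adjacency matrix or `coexnet`.
#' @param truth Truth list from [generate_dataset()].
#' @return List with `precision`, `n_edges`, `n_true`,
#'   `n_confounded` (edges that are true confounded cross-module pairs).
#' @export
within_module_precision <- function(A, truth) {
  A <- resolve_adjacency(A)
  genes <- rownames(A)
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  n_edges <- nrow(idx)
  if (!n_edges)
    return(list(precision = NA_real_, n_edges = 0L, n_true = 0L,
                n_confounded = 0L))
  mod <- truth$module[genes]
  same <- !is.na(mod[idx[, 1L]]) & !is.na(mod[idx[, 2L]]) &
    mod[idx[, 1L]] == mod[idx[, 2L]]
  key <- function(p) paste(pmin(p[, 1L], p[, 2L]),
                           pmax(p[, 1L], p[, 2L]))
  edge_key <- key(cbind(genes[idx[, 1L]], genes[idx[, 2L]]))
  conf_key <- if (nrow(truth$confounded_pairs))
    key(truth$confounded_pairs) else character(0)
  list(precision = mean(same), n_edges = n_edges,
       n_true = as.integer(sum(same)),
       n_confounded = as.integer(sum(edge_key %in% conf_key)))
}
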