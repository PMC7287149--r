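---
title: "Core co-expression networks by centralization within sub-experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core co-expression networks by centralization within sub-experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csenet)
```

## The model

Expression compendia pool assays from many *sub-experiments* — groups of
biological replicates observed under identical settings (a tissue, a
treatment, a developmental stage).  Write `x_ijk` for the normalized
expression of gene *i* in replicate *k* of sub-experiment *j*.  Any
condition affects the *mean* of `x_ij.`; co-regulation acts on the
replicate-level fluctuations around that mean.  Pooled-data correlation
mixes both sources, so two genes that merely respond to the same
treatments can out-correlate genuinely co-regulated pairs.

Centralization within sub-experiments (CSE) subtracts, per gene, the
within-sub-experiment mean:

$$x^{CSE}_{ijk} = x_{ijk} - \bar x_{ij\cdot}.$$

The transformed data have *exactly* zero mean in every
(gene, sub-experiment) cell, so every between-condition mean difference
— treatment, tissue, batch — is removed identically, not merely
estimated away.  CSE is idempotent, invariant to per-cell constant
shifts, and centers without rescaling (genes keep their replicate-level
variance; the aim is to remove location effects, not to standardize).
The price is information: each sub-experiment of size $r_j$ loses one
degree of freedom, so $s$ sub-experiments of $r$ replicates leave
$s(r-1)$ effective samples, and small compendia pay proportionally more.

## Estimators and network construction

Pairwise association can be estimated by Pearson correlation (the
default), full-order partial correlation, biweight midcorrelation, or
topological overlap of a biweight-midcorrelation network:

* **Partial correlation** is computed from the (pseudo-)inverse
  $\Omega$ of the gene correlation matrix as
  $\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$.  When the
  matrix is singular (more genes than samples, collinear genes) the
  Moore–Penrose pseudo-inverse is used with a deterministic relative
  singular-value cutoff of 1e-10, and a warning is raised; we document
  this contract rather than assert equivalence with any particular
  shrinkage scheme in the p ≈ n regime.
* **Biweight midcorrelation** uses median/MAD standardization with the
  standard Tukey tuning constant 9; genes with MAD = 0 cannot be
  standardized and fall back to Pearson for their pairs.
* **TOM** uses the unsigned convention throughout: soft adjacency
  $a_{ij} = |c_{ij}|^{\text{power}}$.  Powers are caller-supplied (5 for
  whole-data networks; 6 and 11 are conventional for centralized and
  non-centralized tissue-consensus sub-networks respectively); no
  automatic scale-free fit is performed, keeping the estimator fully
  deterministic.  Consensus networks take the element-wise minimum of
  per-subset TOMs.

Networks are binarized by **sparsity control**: the
$\lfloor\omega M\rfloor$ pairs with the largest absolute scores become
edges, $M = \binom{n}{2}$.  This is implemented as exact
order-statistic selection — the fixed point that iterative
threshold-adjustment schemes converge to — and is deterministic under
ties (pairs sorted by absolute score, then gene indices).  The realized
cut-off α is reported.  A fixed-cutoff mode (strict inequality,
e.g. 0.82 for condition-specific stress networks) and an intersection
of condition networks (edge kept iff present in all) cover the
condition-specific workflow.

**Bootstrap aggregation** resamples samples with replacement B times
(B = 50 conventionally), thresholds each resample at ω, and aggregates
edge indicators into counts in 0..B.  The final cut-off β is the
smallest count for which the realized sparsity does not exceed ω — the
conservative direction, chosen because no integer cut-off generally
hits ω exactly.  One master seed spawns a per-replicate sub-seed
stream, so enlarging B extends rather than reshuffles the resamples.

## Evaluation

All networks under comparison share the same sparsity ω, so a
sub-network with $M$ possible edges has, under a random network, edge
count $K \sim \mathrm{Bin}(M, \omega)$.  A gene set is *pronounced*
when $K > \omega M$; significance is the exact one-sided binomial tail.
Between-set tests use the bipartite possible-edge count
$M = n_1 n_2$ with shared genes removed from both sets — the simplest
null consistent with random edge placement; the quantity is not
otherwise canonical, so we state it.  Two networks are compared by a
two-sided Fisher exact test on their edge counts (or non-isolated node
counts) at equal $M$; proportions by the pooled two-proportion z.
Catalog-wide runs report Benjamini–Hochberg q-values computed
separately within the within-set and between-set families, with raw
p-values remaining the primary column.  Per-gene category tests use the
unconditional $\mathrm{Bin}(m, \omega)$ null by default; a
degree-conditioned hypergeometric variant is available behind a flag
for users who prefer conditioning on the observed degree.

Guilt-by-association profiling of a single gene compares, per
functional category, the category's share among the gene's neighbours
(n1 = degree) with its share of the annotated universe (n2 = universe
size) by the two-proportion z — over-represented categories among the
neighbours of an unannotated gene suggest its function.

## Communities

Reference communities are built on the centralized network with
Walktrap (random-walk length 4, the algorithm's standard setting;
dendrogram cut at maximal modularity).  Isolated nodes are excluded and
labelled "unassigned" rather than forced into singleton communities,
matching the convention of visualizing only nodes with at least one
edge.  The partition can be overlaid onto condition-specific networks
(per-node community labels, occupancy counts, optional shared-gene
flags) and screened for stress enrichment per community via the
two-proportion z.

## The synthetic generator

`generate_dataset()` draws

$$x_{ijk} = \mu_i + \beta_i\,\delta_j + \lambda\,f_{m(i),jk} + \varepsilon_{ijk},$$

with a latent factor $f$ per module per replicate (rank-1 structure,
the simplest mechanism giving exchangeable within-module correlation
$\lambda^2/(\lambda^2+\sigma^2)$), treatment effects $\delta_j$ fixed
within each sub-experiment and shared by all responsive genes
($\beta_i = 1$), and Gaussian noise.  The treatment term is constant
across replicates — exactly the component CSE removes — so responsive
genes in different modules are spuriously correlated at
$\beta^2\mathrm{Var}(\delta) / (\beta^2\mathrm{Var}(\delta)+\lambda^2+\sigma^2)$
before centralization and uncorrelated after it.

Defaults emulate a compendium-like design at desk scale: 300 genes, 10
modules of 15, $\lambda = \sigma = 1$ (within-module correlation 0.5),
40 sub-experiments of 3 replicates, 50 responsive genes spread over the
whole universe so that responsive pairs span modules, treatment-effect
standard deviation 3 (condition effects dominating single-gene noise,
as in real compendia), baseline $\mu = 8$ on a log2-like scale.  The
generator emulates the *structure* that matters to CSE — replicate
groups, shared condition effects, module factors; it does not model
microarray probe effects, saturation, or count noise, so passing tests
demonstrate the removal of condition-driven false edges, not robustness
to platform artifacts.

One behaviour of the model is worth knowing when interpreting
validation runs: all pairs of a module share a single factor
realization, so per-module edge counts in a sparsity-controlled network
are strongly dependent — a module whose factor happens to have low
sample variance claims few of the shared edge budget.  Across seeds the
minimum per-module edge count varies widely even though average
recovery is essentially perfect; set-level significance thresholds
should be read with that dependence in mind.

## Numerical choices and degenerate inputs

* Quantile normalization maps every column onto the mean of order
  statistics; ties receive the mean of the reference values at their
  tied ranks (rank-average dialect — deterministic and symmetric; other
  dialects exist upstream and equivalence cannot be tested from data).
  Expression input is assumed already log-scaled; nothing is
  log-transformed silently.
* Sub-experiments of size 1 centralize to exactly 0 and are kept with a
  warning by default (`drop_singletons` removes them, since all-zero
  samples dilute correlations); the choice is the user's.
* Zero-variance genes get zero correlation rows (unit diagonal) and are
  reported; in bootstrap resamples this is applied per replicate.
* Tissue-dominance classification uses the raw (non-centralized)
  matrix, because dominance is defined by absolute tissue expression,
  which centralization erases; the spread estimate $s_\Delta$ is the
  sample standard deviation (n − 1) of all per-gene differences.
* All binomial and Fisher computations are exact, never
  normal-approximated; the two-proportion z is the only asymptotic
  test, kept because its pooled form is the field's convention for
  proportion screens.
* Edge lists canonicalize unordered pairs (lexicographically smaller
  gene first) for diff-stable output.

## Problem sizes

The shipped validation suite runs entirely on generated data: 225-gene
score matrices for sparsity exactness, the 300-gene default synthetic
config for end-to-end recovery, 2,000 simulated 30-gene networks for
type-I calibration, and 50-repetition bootstraps on 22 x 60 matrices.
These sizes were chosen to exercise every code path at full statistical
resolution while keeping a complete run in the minutes range on a
single core; the estimators themselves are dense-matrix operations that
scale to the ~1,000-gene sets typical of curated organelle studies
without modification.

## Known limitations

* CSE removes *all* between-condition information by construction;
  condition-specific biology must be recovered by overlaying the
  reference communities onto non-centralized networks, which is exactly
  the intended workflow.
* Partial correlation at p ≫ n rests on the pseudo-inverse contract
  above and is not a substitute for shrinkage estimators when the
  latter are required.
* The bootstrap β rule controls sparsity from below; realized sparsity
  can sit below ω when counts are heavily tied.
* The generator's Gaussian, rank-1 modules are a deliberately minimal
  co-expression mechanism; correlated noise across genes, overlapping
  modules and heavy-tailed noise are out of scope.
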