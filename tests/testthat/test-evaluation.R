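test_that("edge counting within and between sets is exact", {
  A <- adj_from_edges(6, list(c("g001", "g002"), c("g002", "g003"),
                              c("g001", "g003"), c("g004", "g005")))
  tri <- count_edges_within(A, gene_ids(3))
  expect_equal(tri$K, 3); expect_equal(tri$M, 3)
  indep <- count_edges_within(A, c("g004", "g006"))
  expect_equal(indep$K, 0)
  five <- count_edges_within(A, gene_ids(5))
  expect_equal(five$K, 4); expect_equal(five$M, 10)

  expect_warning(count_edges_within(A, c(gene_ids(3), "absent")), "dropped")
  expect_error(suppressWarnings(count_edges_within(A, c("g001", "absent"))),
               "fewer than 2")

  # complete bipartite 2 x 3
  B <- adj_from_edges(5, unlist(lapply(c("g001", "g002"), function(a)
    lapply(c("g003", "g004", "g005"), function(b) c(a, b))),
    recursive = FALSE))
  cb <- count_edges_between(B, c("g001", "g002"), c("g003", "g004", "g005"))
  expect_equal(cb$K, 6); expect_equal(cb$M, 6)
  none <- count_edges_between(A, c("g001", "g002"), c("g005", "g006"))
  expect_equal(none$K, 0)
  one <- count_edges_between(A, gene_ids(4)[4], c("g005", "g006"))
  expect_equal(one$K, 1)
  # overlapping sets: shared genes removed from both sides, with warning
  expect_warning(ov <- count_edges_between(A, c("g001", "g002"),
                                           c("g002", "g003")),
                 "removed from both")
  expect_equal(ov$K, 1)          # only the g001-g003 edge remains eligible
  expect_equal(ov$M, 1)
  expect_error(suppressWarnings(
    count_edges_between(A, gene_ids(3), gene_ids(3))), "at least one")
})

test_that("pronounced test equals binomial tail summation on all small instances", {
  for (M in c(1, 5, 10, 20, 30)) {
    for (K in 0:M) {
      for (omega in c(0.005, 0.1, 0.5)) {
        t_g <- pronounced_test(K, M, omega, "greater")
        expect_equal(t_g$p_value, binom_tail_oracle(K, M, omega, "greater"),
                     tolerance = 1e-12)
        t_l <- pronounced_test(K, M, omega, "less")
        expect_equal(t_l$p_value, binom_tail_oracle(K, M, omega, "less"),
                     tolerance = 1e-12)
        expect_equal(t_g$pronounced, K > omega * M)
      }
    }
  }
  # hand case from the binomial pmf: P(K >= 2), M = 10, omega = 0.005
  expect_equal(pronounced_test(2, 10, 0.005)$p_value,
               1 - 0.995^10 - 10 * 0.005 * 0.995^9, tolerance = 1e-12)
  expect_equal(pronounced_test(0, 10, 0.005)$p_value, 1)
  expect_true(pronounced_test(1, 10, 0.005)$pronounced)  # 1 > 0.05
})

test_that("Fisher comparisons equal hypergeometric enumeration on small tables", {
  for (M in c(1, 3, 5, 10, 17, 30)) {
    for (k1 in unique(round(seq(0, M, length.out = 6)))) {
      for (k2 in unique(round(seq(0, M, length.out = 6)))) {
        expect_equal(compare_networks_fisher(k1, k2, M),
                     fisher_oracle(k1, k2, M), tolerance = 1e-9)
      }
    }
  }
  expect_equal(compare_networks_fisher(4, 4, 9), 1)
  expect_equal(compare_networks_fisher(0, 5, 5), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(compare_networks_fisher(3, 8, 20),
               compare_networks_fisher(8, 3, 20))
  expect_equal(compare_node_counts_fisher(10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(compare_node_counts_fisher(7, 12, 7), 1)
  expect_equal(compare_node_counts_fisher(3, 15, 9),
               compare_node_counts_fisher(9, 15, 3))
})

test_that("two-proportion z matches the pooled-variance formula", {
  r <- two_proportion_z(30, 60, 10, 40)
  expect_equal(r$pi_pooled, 0.4)
  expect_equal(r$z, 2.5)          # hand: (0.5-0.25)/sqrt(.4*.6*(1/60+1/40))
  expect_equal(r$p_value, 2 * pnorm(-2.5))

  eq <- two_proportion_z(5, 10, 10, 20)
  expect_equal(eq$z, 0); expect_equal(eq$p_value, 1)
  expect_equal(two_proportion_z(10, 40, 30, 60)$z, -2.5)  # antisymmetry
  expect_warning(r0 <- two_proportion_z(0, 10, 0, 20), "pooled")
  expect_equal(r0$p_value, 1)
})

test_that("gene-category test uses a Bin(m, omega) null on the gene's category edges", {
  A <- adj_from_edges(8, list(c("g001", "g002"), c("g001", "g003"),
                              c("g001", "g004"), c("g001", "g008")))
  # K = 3 edges into the category {g002..g006}; gene itself excluded
  res <- gene_category_test("g001", c("g001", gene_ids(6)[2:6]), A,
                            omega = 0.05)
  expect_equal(res$K, 3); expect_equal(res$M, 5)
  expect_equal(res$p_value, binom_tail_oracle(3, 5, 0.05, "greater"),
               tolerance = 1e-12)

  # m = 1, K = 1 -> p = omega (single-trial binomial)
  res1 <- gene_category_test("g001", "g002", A, omega = 0.05)
  expect_equal(res1$p_value, 0.05)
  # K = 0 with alternative greater -> p = 1
  res0 <- gene_category_test("g002", "g008", A, omega = 0.05)
  expect_equal(res0$p_value, 1)
  expect_error(gene_category_test("absent", "g002", A, 0.05), "not in network")

  # degree-conditioned variant: hypergeometric by construction
  resc <- gene_category_test("g001", gene_ids(6)[2:6], A, omega = 0.05,
                             conditional = TRUE)
  d <- 4; m <- 5; n_other <- 7
  expect_equal(resc$p_value,
               sum(dhyper(3:min(m, d), m, n_other - m, d)),
               tolerance = 1e-12)
})

test_that("guilt-by-association profiles delegate to the z test per category", {
  # gene g001 with degree 4: neighbors g002..g004 in category A, g005 in B
  A <- adj_from_edges(10, lapply(gene_ids(5)[2:5], function(b) c("g001", b)))
  ann <- setNames(c("B", "A", "A", "A", "B", rep("B", 5)), gene_ids(10))
  prof <- guilt_by_association_profile("g001", A, ann)
  expect_setequal(prof$category, c("A", "B"))
  a_row <- prof[prof$category == "A", ]
  expect_equal(a_row$neighbors, 3)
  expect_equal(a_row$degree, 4)
  ref <- two_proportion_z(3, 4, 3, 10)
  expect_equal(a_row$z, ref$z)
  expect_equal(a_row$p_value, ref$p_value)
  expect_gt(a_row$z, 0)    # over-represented among neighbors

  # neighbor proportions equal to background -> z = 0 everywhere
  ann2 <- setNames(rep(c("A", "B"), 5), gene_ids(10))
  A2 <- adj_from_edges(10, list(c("g001", "g002"), c("g001", "g003")))
  # neighbors g002 (B), g003 (A): proportions 1/2 vs background 1/2
  prof2 <- guilt_by_association_profile("g001", A2, ann2)
  expect_true(all(prof2$z == 0))

  expect_error(guilt_by_association_profile("g010", A2, ann2), "no edges")
})

test_that("catalog evaluation flags true modules and adjusts per family", {
  sim <- generate_dataset(generator_config(
    n_genes = 60, module_sizes = rep(10, 3), s = 20, r = 3,
    n_confounded = 0, lambda = 2, sigma = 1, seed = 21))
  net <- coexpression_network(sim$expression, sim$design,
                              method = "pearson", omega = 0.05,
                              centralize = TRUE)
  ann <- generate_annotations(sim$truth, seed = 21)
  tab <- evaluate_catalog(net, ann$catalog, omega = 0.05)
  within <- tab[tab$type == "within", ]
  mods <- within[grepl("^module", within$set), ]
  expect_true(all(mods$pronounced))
  expect_true(all(mods$p_value < 1e-4))
  expect_true(all(c("p_value", "q_value") %in% colnames(tab)))
  # BH within each family separately
  expect_equal(within$q_value, p.adjust(within$p_value, "BH"))
  btw <- tab[tab$type == "between", ]
  expect_equal(btw$q_value, p.adjust(btw$p_value, "BH"))
  expect_equal(nrow(btw), choose(length(ann$catalog), 2))

  one <- evaluate_catalog(net, ann$catalog[1], omega = 0.05)
  expect_equal(nrow(one), 1)
  expect_warning(
    evaluate_catalog(net, list(tiny = "g001", ok = gene_ids(10)), 0.05),
    "skipped")
})

test_that("type-I error of the pronounced test is calibrated on random networks", {
  # random networks at exact sparsity; fixed 10-gene focal set (M = 45)
  n <- 30; omega <- 0.1
  m_edges <- floor(omega * choose(n, 2))
  set.seed(22)
  hits <- 0; ks <- numeric(400)
  for (i in 1:400) {
    A <- rand_adjacency(n, m_edges)
    K <- count_edges_within(A, gene_ids(10))$K
    ks[i] <- K
    if (pronounced_test(K, 45, omega)$p_value <= 0.05) hits <- hits + 1
  }
  expect_lte(hits / 400, 0.07)
  # expected-edge identity: mean K ~= omega * M
  expect_equal(mean(ks), omega * 45, tolerance = 0.05)
})
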