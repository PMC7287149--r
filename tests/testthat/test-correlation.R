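test_that("pearson matrix matches hand-computed and boundary cases", {
  x <- rbind(a = c(1, 2, 3), b = c(1, 3, 2), dup = c(1, 2, 3),
             neg = c(-1, -2, -3))
  colnames(x) <- paste0("s", 1:3)
  C <- pearson_matrix(x)
  expect_equal(C["a", "b"], 0.5)        # product-moment by hand
  expect_equal(C["a", "dup"], 1)
  expect_equal(C["a", "neg"], -1)
  expect_equal(C, t(C))
})

test_that("zero-variance genes get zero rows with unit diagonal", {
  x <- rand_expr(4, 10, seed = 8)
  x["g002", ] <- 5
  expect_warning(C <- pearson_matrix(x), "g002")
  expect_true(all(C["g002", -2] == 0) && all(C[-2, "g002"] == 0))
  expect_equal(C["g002", "g002"], 1)
  expect_equal(attr(C, "zero_variance"), "g002")
})

test_that("pearson and bicor are invariant to positive affine rescaling", {
  x <- rand_expr(6, 40, seed = 9)
  y <- x * rep(c(2, 0.5, 3, 1, 10, 0.1), ncol(x)) + rep(1:6, ncol(x))
  expect_equal(unclass(pearson_matrix(y)), unclass(pearson_matrix(x)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(bicor_matrix(y)), unclass(bicor_matrix(x)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("partial correlation equals Pearson for 2 genes and is zero across a Markov chain", {
  x <- rand_expr(2, 10, seed = 10)
  expect_equal(partial_matrix(x)[1, 2], pearson_matrix(x)[1, 2])

  # data engineered to have exactly the factorized correlation
  # [[1,.6,.36],[.6,1,.6],[.36,.6,1]]: conditioning on the middle gene
  # must annihilate the 1-3 association
  C <- rbind(c(1, .6, .36), c(.6, 1, .6), c(.36, .6, 1))
  n <- 50
  set.seed(11)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(3 * n), n, 3))))[, 2:4]
  W <- t(Q) * sqrt(n - 1)            # rows: mean 0, identity sample covariance
  x3 <- t(chol(C)) %*% W
  dimnames(x3) <- list(gene_ids(3), sprintf("s%03d", 1:n))
  expect_equal(unclass(pearson_matrix(x3)), C, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(partial_matrix(x3)["g001", "g003"], 0, tolerance = 1e-8)
})

test_that("partial correlation agrees with the first-order closed form on 3-gene data", {
  for (seed in 1:10) {
    x <- rand_expr(3, 25, seed = 100 + seed)
    r <- pearson_matrix(x)
    p <- partial_matrix(x)
    for (ij in list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))) {
      i <- ij[1]; j <- ij[2]; k <- ij[3]
      expected <- (r[i, j] - r[i, k] * r[j, k]) /
        sqrt((1 - r[i, k]^2) * (1 - r[j, k]^2))
      expect_equal(p[i, j], expected, tolerance = 1e-8)
    }
  }
})

test_that("partial correlation recovers the sign pattern of a sparse precision matrix", {
  # chain precision: direct links 1-2, 2-3, 3-4 only, negative partials off
  p <- 4
  Omega <- diag(p) * 2
  for (i in 1:(p - 1)) Omega[i, i + 1] <- Omega[i + 1, i] <- -0.9
  Sigma <- solve(Omega)
  set.seed(12)
  x <- t(MASS::mvrnorm(2000, rep(0, p), Sigma))
  dimnames(x) <- list(gene_ids(p), sprintf("s%04d", 1:2000))
  P <- partial_matrix(x)
  for (i in 1:(p - 1)) expect_gt(P[i, i + 1], 0.2)   # direct edges large +
  expect_lt(abs(P[1, 3]), 0.1)                       # non-edges near 0
  expect_lt(abs(P[1, 4]), 0.1)
  expect_lt(abs(P[2, 4]), 0.1)
})

test_that("singular systems fall back to the pseudo-inverse with a warning", {
  x <- rand_expr(10, 4, seed = 13)  # p > n
  expect_warning(P <- partial_matrix(x), "pseudo-inverse")
  expect_equal(P, t(P))
  expect_true(all(abs(P) <= 1 + 1e-12))
})

test_that("bicor handles affine, duplicated, negated and MAD-0 genes", {
  set.seed(14)
  base <- rnorm(30)
  x <- rbind(x = base, y = 2 * base + 1, neg = -base, flat = rep(1, 30))
  colnames(x) <- sprintf("s%02d", 1:30)
  expect_warning(C <- bicor_matrix(x), "MAD = 0")
  expect_equal(C["x", "y"], 1)
  expect_equal(C["x", "neg"], -1)
  expect_equal(attr(C, "mad_zero"), "flat")
})

test_that("bicor resists a gross outlier better than Pearson", {
  set.seed(15)
  a <- rnorm(30); b <- 0.8 * a + rnorm(30, 0, 0.5)
  clean <- rbind(a = a, b = b)
  colnames(clean) <- sprintf("s%02d", 1:30)
  r_clean <- pearson_matrix(clean)["a", "b"]
  dirty <- clean
  dirty["b", 1] <- 50
  r_dirty <- pearson_matrix(dirty)["a", "b"]
  bc <- bicor_matrix(dirty)["a", "b"]
  expect_lt(abs(bc - r_clean), abs(r_dirty - r_clean))
})

test_that("TOM formula holds on boundary cases and stays in [0, 1]", {
  # 2 genes with |c| = 1: l = 0, k = 1 -> TOM = (0 + 1)/(1 + 1 - 1) = 1
  C2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(gene_ids(2), gene_ids(2)))
  expect_equal(tom_similarity(C2, power = 5)[1, 2], 1)

  C0 <- diag(4); dimnames(C0) <- list(gene_ids(4), gene_ids(4))
  T0 <- tom_similarity(C0, power = 5)
  expect_true(all(T0[upper.tri(T0)] == 0))

  T1 <- tom_similarity(rand_scores(12, seed = 16) * 0.9, power = 3)
  expect_true(all(T1 >= 0 & T1 <= 1 + 1e-12))
  expect_error(tom_similarity(C2, power = 0), "positive")
})

test_that("TOM agrees with a brute-force triple loop", {
  for (seed in 1:3) {
    C <- rand_scores(10, seed = 200 + seed) * 0.95
    diag(C) <- 1
    power <- 5
    A <- abs(C)^power; diag(A) <- 0
    n <- nrow(A)
    ref <- diag(n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
      ref[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
    }
    dimnames(ref) <- dimnames(C)
    expect_equal(unclass(tom_similarity(C, power)), ref,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("consensus TOM is the element-wise minimum, associative and commutative", {
  m1 <- matrix(c(1, .5, .5, 1), 2, 2, dimnames = list(gene_ids(2), gene_ids(2)))
  m2 <- matrix(c(1, .2, .2, 1), 2, 2, dimnames = dimnames(m1))
  expect_equal(unclass(consensus_tom(list(m1, m2))), pmin(m1, m2),
               ignore_attr = TRUE)
  expect_equal(consensus_tom(list(m1, m1)), m1, ignore_attr = TRUE)

  m3 <- rand_scores(2, seed = 17)
  abc <- consensus_tom(list(m1, m2, m3))
  expect_equal(abc, consensus_tom(list(m3, consensus_tom(list(m2, m1)))),
               ignore_attr = TRUE)
  for (m in list(m1, m2, m3))
    expect_true(all(unclass(abc) <= unclass(m) + 1e-15))

  bad <- m2; rownames(bad) <- rev(rownames(bad)); colnames(bad) <- rownames(bad)
  expect_error(consensus_tom(list(m1, bad)), "mismatch")
})
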