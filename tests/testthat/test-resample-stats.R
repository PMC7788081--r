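norm_em <- function(m) normalize_umi(make_em(m))

test_that("pseudobulk respects symmetry, exhaustive sampling, and seeds", {
  # identical cells -> profile equals that cell's vector for any seed
  m <- matrix(rep(c(4, 1, 0, 2), 6), 4, 6)
  em <- norm_em(m)
  set.seed(42)
  p <- pseudobulk(em, colnames(em$counts), size = 3)
  expect_equal(as.numeric(p), as.numeric(em$normalized[, 1]), tolerance = 1e-12)

  # size = population size without replacement -> exact population mean
  em2 <- norm_em(rand_counts(20, 10, seed = 4))
  set.seed(1)
  p2 <- pseudobulk(em2, colnames(em2$counts), size = 10)
  expect_equal(as.numeric(p2), unname(Matrix::rowMeans(em2$normalized)),
               tolerance = 1e-12)
  expect_false(attr(p2, "replace"))

  # same seed -> identical; different seeds -> different on heterogeneous pop
  set.seed(7); a <- pseudobulk(em2, colnames(em2$counts), size = 4)
  set.seed(7); b <- pseudobulk(em2, colnames(em2$counts), size = 4)
  set.seed(8); d <- pseudobulk(em2, colnames(em2$counts), size = 4)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, d)))
})

test_that("euclidean channel matches a naive elementwise oracle", {
  p <- setNames(c(3, 0), c("a", "b")); q <- setNames(c(0, -4), c("a", "b"))
  expect_identical(stat_euclidean(p, p), 0)
  expect_identical(stat_euclidean(p, q), 5)
  set.seed(9)
  g <- sprintf("g%03d", 1:100)
  p <- setNames(runif(100), g); q <- setNames(runif(100), g)
  acc <- 0
  for (i in 1:100) acc <- acc + (p[[i]] - q[[i]])^2
  expect_equal(stat_euclidean(p, q), sqrt(acc), tolerance = 1e-12)
  expect_error(stat_euclidean(p, q, genes = character(0)), "empty gene")
})

test_that("spearman channel is rank-invariant and matches the rank-Pearson oracle", {
  g <- paste0("g", 1:10)
  p <- setNames(c(1, 5, 3, 9, 2, 2, 7, 4, 6, 8), g)
  expect_equal(stat_spearman(p, setNames(exp(p), g)), 1)
  expect_equal(stat_spearman(p, setNames(-p, g)), -1)
  q <- setNames(c(2, 2, 4, 1, 9, 9, 3, 5, 5, 0), g)  # ties
  oracle <- cor(rank(p, ties.method = "average"),
                rank(q, ties.method = "average"))
  expect_equal(stat_spearman(p, q), oracle, tolerance = 1e-12)
  expect_error(stat_spearman(p, setNames(rep(1, 10), g)), "constant")
})

test_that("PC-distance channel weights components by explained variance", {
  g <- c("a", "b")
  basis <- structure(list(rotation = diag(2), center = c(0, 0),
                          weights = c(0.5, 0.5), genes = g),
                     class = "pca_basis")
  rownames(basis$rotation) <- g
  p <- setNames(c(2, 0), g); q <- setNames(c(0, 0), g)
  expect_equal(stat_pc_dist(p, p, basis), 0)
  expect_equal(stat_pc_dist(p, q, basis), sqrt(2), tolerance = 1e-12)
  # zero weight annihilates the second component
  basis$weights <- c(1, 0)
  r <- setNames(c(0, 100), g)
  expect_equal(stat_pc_dist(q, r, basis), 0, tolerance = 1e-12)
})

test_that("fitted PCA basis reproduces weighted distances from first principles", {
  em <- norm_em(rand_counts(30, 25, lambda = 3, seed = 6))
  genes <- sort(rownames(em$counts))
  basis <- fit_pca_basis(em, genes, n_pc = 5)
  p <- setNames(as.numeric(em$normalized[genes, 1]), genes)
  q <- setNames(as.numeric(em$normalized[genes, 2]), genes)
  pr <- stats::prcomp(t(as.matrix(em$normalized[genes, ])), center = TRUE)
  d <- (p - pr$center) %*% pr$rotation[, 1:5] -
       (q - pr$center) %*% pr$rotation[, 1:5]
  w <- pr$sdev^2 / sum(pr$sdev^2)
  expect_equal(stat_pc_dist(p, q, basis), sqrt(sum(w[1:5] * d^2)),
               tolerance = 1e-8)
})

test_that("gene-set profile channel composes recovery AUCs", {
  g <- sprintf("g%02d", 1:30)
  sets <- list(S1 = g[1:5], S2 = g[10:20], S3 = g[c(2, 25, 30)],
               S4 = g[15:18], S5 = g[28:30])
  set.seed(10)
  p <- setNames(runif(30), g); q <- setNames(runif(30), g)
  expect_equal(stat_gsea_profile(p, p, sets, L = 10), 0)
  a <- vapply(sets, function(s) oracle_auc(rank_genes(p), s, 10)$norm, numeric(1))
  b <- vapply(sets, function(s) oracle_auc(rank_genes(q), s, 10)$norm, numeric(1))
  expect_equal(stat_gsea_profile(p, q, sets, L = 10), sqrt(sum((a - b)^2)),
               tolerance = 1e-12)
})

test_that("compiled kernels agree with their plain-R counterparts", {
  set.seed(13)
  X <- matrix(rnorm(40 * 25), 40, 25)  # 40 cells x 25 genes
  idx <- t(replicate(15, sample.int(40, 5)))
  P <- ccimap:::.profile_means_cpp(X, idx)
  for (i in 1:15)
    expect_equal(P[i, ], colMeans(X[idx[i, ], ]), tolerance = 1e-12)
  Q <- ccimap:::.profile_means_cpp(X, t(replicate(15, sample.int(40, 5))))
  rho <- ccimap:::.spearman_rows_cpp(P, Q)
  for (i in 1:15)
    expect_equal(rho[i], cor(P[i, ], Q[i, ], method = "spearman"),
                 tolerance = 1e-12)
  g <- sprintf("g%02d", 1:25)
  sets <- list(a = 1:4, b = c(7L, 20L, 25L), c = 10:18)
  A <- ccimap:::.auc_rows_cpp(P, sets, 12L)
  for (i in 1:15) for (s in seq_along(sets)) {
    prof <- setNames(P[i, ], g)
    expect_equal(A[i, s], oracle_auc(rank_genes(prof), g[sets[[s]]], 12)$norm,
                 tolerance = 1e-12)
  }
})

test_that("empirical nulls have the right shape, determinism, and orientation", {
  sim <- small_sim(seed = 3, n_genes = 200, cells_per_pop = 40)
  em <- sim$ref; lab <- sim$atlas$labels
  nul <- build_null(em, lab, "GMP", "MEP", "euclidean", n_resamples = 200,
                    seed = 5)
  expect_length(nul$values, 200)
  expect_identical(nul$median, median(nul$values))
  expect_identical(nul$orientation, "distance")
  expect_true(all(nul$values >= 0))
  nul2 <- build_null(em, lab, "GMP", "MEP", "euclidean", n_resamples = 200,
                     seed = 5)
  expect_identical(nul$values, nul2$values)
  sp <- build_null(em, lab, "GMP", "MEP", "spearman", n_resamples = 150,
                   seed = 5)
  expect_identical(sp$orientation, "similarity")
  expect_true(all(abs(sp$values) <= 1))
  expect_warning(build_null(em, lab, "GMP", "MEP", "euclidean",
                            n_resamples = 50, seed = 1), "unstable")
  expect_error(build_null(em, lab, "GMP", "MEP", "euclidean",
                          n_resamples = 1, seed = 1), "at least 2")
})

test_that("populations of identical cells give a degenerate null at the analytic value", {
  m <- cbind(matrix(rep(c(5, 1, 0, 3), 10), 4, 10),
             matrix(rep(c(0, 2, 6, 1), 10), 4, 10))
  colnames(m) <- paste0("c", 1:20)
  rownames(m) <- paste0("g", 1:4)
  em <- normalize_umi(expr_matrix(m))
  lab <- data.frame(barcode = colnames(m),
                    population = rep(c("A", "B"), each = 10))
  analytic <- stat_euclidean(
    setNames(as.numeric(em$normalized[, 1]), rownames(m)),
    setNames(as.numeric(em$normalized[, 11]), rownames(m)))
  nul <- suppressWarnings(build_null(em, lab, "A", "B", "euclidean",
                                     n_resamples = 50, size = 5, seed = 2))
  expect_equal(unique(round(nul$values, 10)), round(analytic, 10))
})

test_that("self-comparison medians are below planted-shift medians", {
  hits <- 0
  for (s in 1:5) {
    atlas <- simulate_atlas(seed = s, n_genes = 300, cells_per_pop = 50)
    em <- normalize_umi(atlas$matrix)
    lab <- atlas$labels
    self_med <- build_null(em, lab, "GMP", "GMP", "euclidean",
                           n_resamples = 200, seed = s)$median
    other_med <- build_null(em, lab, "GMP", "MEP", "euclidean",
                            n_resamples = 200, seed = s)$median
    if (self_med < other_med) hits <- hits + 1
  }
  expect_equal(hits, 5)
})
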