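mock_null <- function(values, statistic, query = "Q", reference) {
  structure(list(values = values, median = median(values),
                 orientation = stat_orientation(statistic),
                 statistic = statistic, query = query, reference = reference,
                 n_resamples = length(values), size = 30),
            class = "empirical_null")
}

test_that("channel likelihoods equal hand-counted tail fractions", {
  # distance channel: S* = min median = 2.5 (ref A)
  nulls <- list(
    mock_null(c(1, 2, 2, 3, 3, 4, 4, 5, 5, 6), "euclidean", reference = "A"),
    mock_null(c(2, 2, 3, 3, 4, 5, 6, 7, 8, 9), "euclidean", reference = "B"),
    mock_null(c(10, 11, 12, 13, 14, 15, 16, 17, 18, 19), "euclidean",
              reference = "C"))
  L <- channel_likelihood(nulls)
  # medians: A 3.5, B 4.5, C 14.5 -> S* = 3.5
  # A: 5 of 10 values <= 3.5; B: 4 of 10; C: none -> floor
  expect_equal(unname(L), c(0.5, 0.4, 1e-6))
  expect_identical(names(L), c("A", "B", "C"))

  # similarity channel: S* = max median
  s_nulls <- list(
    mock_null(c(0.1, 0.2, 0.3, 0.4), "spearman", reference = "A"),
    mock_null(c(0.5, 0.6, 0.7, 0.8), "spearman", reference = "B"))
  Ls <- channel_likelihood(s_nulls)
  # medians 0.25, 0.65 -> S* = 0.65; A: 0 of 4 >= 0.65 -> floor; B: 2 of 4
  expect_equal(unname(Ls), c(1e-6, 0.5))

  expect_error(channel_likelihood(list(nulls[[1]], s_nulls[[1]])), "mixed")
  expect_error(channel_likelihood(list()), "no empirical nulls")
})

test_that("the best reference's own median splits its null near 0.5", {
  set.seed(21)
  vals <- rnorm(1001, 5, 1)
  nulls <- list(mock_null(vals, "euclidean", reference = "best"),
                mock_null(vals + 10, "euclidean", reference = "worse"))
  L <- channel_likelihood(nulls)
  expect_equal(unname(L["best"]), 0.5, tolerance = 0.01)
})

test_that("composite posterior follows the product-of-posteriors arithmetic", {
  lik <- list(ch1 = c(A = 0.8, B = 0.2), ch2 = c(A = 0.6, B = 0.4))
  res <- cci_posterior(lik)
  expect_equal(unname(res$combined), c(0.48, 0.08) / 0.56, tolerance = 1e-12)
  expect_equal(sum(res$combined), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(res$posterior) - 1) < 1e-9))

  # symmetric channels -> (0.5, 0.5)
  sym <- cci_posterior(list(a = c(X = 2, Y = 2), b = c(X = 7, Y = 7)))
  expect_equal(unname(sym$combined), c(0.5, 0.5))

  # single channel with uniform prior reduces to that channel's posterior
  one <- cci_posterior(lik["ch1"])
  expect_equal(one$combined, one$posterior["ch1", ])

  # a non-uniform prior reweights before normalization
  pri <- cci_posterior(lik["ch1"], priors = c(A = 0.25, B = 0.75))
  expect_equal(unname(pri$combined),
               c(0.8 * 0.25, 0.2 * 0.75) / (0.8 * 0.25 + 0.2 * 0.75))
  expect_error(cci_posterior(list(c(A = 1), c(B = 1))), "different reference")
})

test_that("reference permutation equivariance holds exactly at the posterior level", {
  set.seed(22)
  lik <- list(e = setNames(runif(5), LETTERS[1:5]),
              s = setNames(runif(5), LETTERS[1:5]))
  base <- cci_posterior(lik)$combined
  perm <- c("D", "A", "E", "C", "B")
  shuffled <- lapply(lik, function(v) v[perm])
  expect_equal(cci_posterior(shuffled)$combined, base[perm])
})

test_that("counterpart assignment takes the argmax with -L naming and root-ward ties", {
  tree <- default_tree()
  post <- list(
    Q1 = list(combined = c(GMP = 0.9, LMPP = 0.05, MPP = 0.05)),
    Q2 = list(combined = c(MPP = 0.5, LMPP = 0.5)))  # parent MPP wins the tie
  asg <- assign_counterparts(post, tree = tree)
  expect_identical(asg$counterpart, c("GMP", "MPP"))
  expect_identical(asg$label, c("GMP-L", "MPP-L"))
  expect_equal(asg$margin[1], 0.85)
  expect_true(all(endsWith(asg$label, "-L")))
  expect_true(asg$flagged[2])  # zero margin is below the default 0.1
})

test_that("mapping report reads heterogeneity and stemness off the tree", {
  tree <- default_tree()
  asg <- data.frame(query = "Q1", counterpart = "GMP", label = "GMP-L",
                    stringsAsFactors = FALSE)
  rep1 <- mapping_report(asg, tree = tree)
  expect_equal(rep1$per_sample$tree_span, 0)
  expect_equal(rep1$per_sample$n_counterparts, 1)

  asg2 <- data.frame(query = c("Q1", "Q2"),
                     counterpart = c("HSC", "ProB"),
                     label = c("HSC-L", "ProB-L"), stringsAsFactors = FALSE)
  rep2 <- mapping_report(asg2, tree = tree)
  expect_equal(rep2$per_sample$stemness_depth, 0)  # HSC is the root
  expect_equal(rep2$per_sample$tree_span, oracle_tree_dist(tree, "HSC", "ProB"))

  asg3 <- data.frame(query = c("Q1", "Q2", "Q3"),
                     counterpart = c("GMP", "ProB", "MEP"),
                     label = paste0(c("GMP", "ProB", "MEP"), "-L"),
                     stringsAsFactors = FALSE)
  span <- max(outer(asg3$counterpart, asg3$counterpart,
                    Vectorize(function(a, b) oracle_tree_dist(tree, a, b))))
  expect_equal(mapping_report(asg3, tree = tree)$per_sample$tree_span, span)
  expect_error(mapping_report(
    data.frame(query = "Q", counterpart = "nope", label = "nope-L"),
    tree = tree), "absent from tree")
})

test_that("a query identical to a reference population wins by a wide margin", {
  atlas <- simulate_atlas(seed = 4, n_genes = 400, cells_per_pop = 60)
  ref <- normalize_umi(atlas$matrix)
  # query = the GMP cells themselves, relabeled
  gmp <- atlas$labels$barcode[atlas$labels$population == "GMP"]
  qm <- atlas$matrix$counts[, gmp]
  colnames(qm) <- paste0("q_", colnames(qm))
  query <- normalize_umi(expr_matrix(qm))
  qlab <- data.frame(barcode = colnames(qm), population = "QSELF")
  fit <- suppressWarnings(
    cci(ref, atlas$labels, query, qlab, tree = atlas$tree,
        channels = c("euclidean", "spearman", "pc_dist"),
        n_resamples = 400, n_hvg = 400, seed = 9))
  comb <- fit$posteriors$QSELF$combined
  expect_identical(fit$assignments$counterpart, "GMP")
  expect_gte(comb["GMP"] - max(comb[names(comb) != "GMP"]), 0.3)
  expect_true(all(abs(vapply(list(comb), sum, numeric(1)) - 1) < 1e-9))
})

test_that("posterior tables carry one row per query, reference, and channel", {
  sim <- small_sim(seed = 6, n_genes = 250, cells_per_pop = 40,
                   counterparts = c(Q1 = "GMP"))
  fit <- suppressWarnings(
    cci(sim$ref, sim$atlas$labels, sim$query, sim$q$labels,
        gene_sets = sim$sets, tree = sim$atlas$tree,
        n_resamples = 150, n_hvg = 250, seed = 2))
  tab <- posterior_table(fit)
  expect_equal(nrow(tab), 1 * 8 * 4)
  expect_true(all(tab$combined >= 0 & tab$combined <= 1))
  sums <- tapply(tab$posterior, list(tab$query_pop, tab$channel), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
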