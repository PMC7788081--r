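# small in-code fixtures shared across test files

# expr_matrix from a dense genes x cells matrix, naming rows/cols if needed
make_em <- function(m, gene_names = NULL, mito_prefix = "MT-") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  expr_matrix(m, gene_names = gene_names, mito_prefix = mito_prefix)
}

# random count matrix
rand_counts <- function(n_genes, n_cells, lambda = 2, seed = 1) {
  set.seed(seed)
  matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
}

# a small simulated atlas + normalized matrices + queries, for pipeline tests
small_sim <- function(seed = 1, n_genes = 500, cells_per_pop = 60,
                      counterparts = c(Q1 = "GMP", Q2 = "ProB")) {
  atlas <- simulate_atlas(seed = seed, n_genes = n_genes,
                          cells_per_pop = cells_per_pop)
  q <- simulate_queries(atlas, counterparts, cells_per_pop = cells_per_pop,
                        seed = seed + 1)
  list(atlas = atlas, ref = normalize_umi(atlas$matrix),
       query = normalize_umi(q$matrix), q = q,
       sets = simulate_gene_sets(rownames(atlas$matrix$counts),
                                 n_sets = 20, seed = seed + 2))
}

# independent brute-force recovery-curve AUC: literally walk the list
oracle_auc <- function(ranked, set, L) {
  hits <- cumsum(ranked %in% set)
  curve <- vapply(seq_len(L), function(r)
    if (r <= length(hits)) hits[r] else hits[length(hits)], numeric(1))
  raw <- sum(curve)
  m <- min(sum(set %in% ranked), L)
  denom <- sum(pmin(seq_len(L), m))
  list(raw = raw, norm = if (denom > 0) raw / denom else 0)
}

# independent exact binomial upper tail P(X >= k | n, p)
oracle_binom_tail <- function(k, n, p = 0.5) {
  if (k > n) return(0)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

# independent BFS path lengths on a pop_tree
oracle_tree_dist <- function(tree, a, b) {
  adj <- lapply(tree$nodes, function(v)
    unique(c(tree$edges$child[tree$edges$parent == v],
             tree$edges$parent[tree$edges$child == v])))
  names(adj) <- tree$nodes
  dist <- setNames(rep(Inf, length(tree$nodes)), tree$nodes)
  dist[a] <- 0
  frontier <- a
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
      dist[w] <- dist[v] + 1
      nxt <- c(nxt, w)
    }
    frontier <- nxt
  }
  unname(dist[b])
}
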