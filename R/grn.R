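#' Mutual information between expression and pseudotime
#'
#' Plug-in estimate from the joint histogram of equal-frequency bins of the
#' two variables, in bits. A constant vector carries no information and
#' returns 0.
#'
#' @param x per-cell expression values.
#' @param t per-cell pseudotime values (same length).
#' @param bins number of equal-frequency bins per margin (default 10).
#' @return mutual information in bits (>= 0).
#' @export
mutual_info <- function(x, t, bins = 10L) {
  if (length(x) != length(t)) stop("x and t must have the same length")
  if (length(x) < bins) stop("need at least `bins` observations")
  if (any(!is.finite(x)) || any(!is.finite(t))) stop("non-finite values")
  bx <- ef_bin(x, bins)
  bt <- ef_bin(t, bins)
  joint <- table(bx, bt) / length(x)
  px <- rowSums(joint)
  pt <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(pt)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * pt[j]))
  }
  max(0, mi)
}

# equal-frequency binning; ties share a bin via rank averaging
ef_bin <- function(v, bins) {
  if (length(unique(v)) == 1) return(rep(1L, length(v)))
  r <- rank(v, ties.method = "average")
  as.integer(cut(r, breaks = bins, labels = FALSE, include.lowest = TRUE))
}

#' Mutual information from a joint probability table
#'
#' Direct evaluation of `sum p log2(p / (p_row p_col))` on a given joint
#' distribution — used to score pre-binned data and as the definitional
#' form of [mutual_info()].
#'
#' @param joint matrix of joint probabilities (sums to 1) or counts.
#' @return mutual information in bits.
#' @export
mi_from_joint <- function(joint) {
  joint <- joint / sum(joint)
  px <- rowSums(joint)
  pt <- colSums(joint)
  mi <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * pt[j]))
  }
  mi
}

#' Regulator score along a trajectory
#'
#' Ranks a transcriptional regulator by `score = c * m * n`: `c` is the
#' mutual information between the regulator's expression and pseudotime,
#' `m` the mean mutual information between its predicted targets and
#' pseudotime, and `n` the number of targets deemed regulated along the
#' trajectory (target MI exceeding the `quantile` of its own permutation
#' null, built by shuffling pseudotime).
#'
#' @param x normalized `expr_matrix` restricted to trajectory cells, or a
#'   genes x cells matrix.
#' @param regulator gene id of the regulator.
#' @param targets character vector of predicted target gene ids.
#' @param pseudotime per-cell pseudotime (aligned to columns of `x`).
#' @param bins MI bins (default 10).
#' @param quantile permutation-null quantile a target must exceed
#'   (default 0.95).
#' @param n_perm permutations per target (default 100).
#' @param seed optional integer seed for the permutations.
#' @return list with `regulator`, `c`, `m`, `n`, `score`, and `regulated`
#'   (the targets counted in `n`).
#' @export
grn_score <- function(x, regulator, targets, pseudotime, bins = 10L,
                      quantile = 0.95, n_perm = 100L, seed = NULL) {
  m <- as_gene_matrix(x)
  if (length(pseudotime) != ncol(m))
    stop("pseudotime must align with cells")
  if (!regulator %in% rownames(m)) stop("regulator absent: ", regulator)
  if (!is.null(seed)) set.seed(seed)
  c_val <- mutual_info(m[regulator, ], pseudotime, bins)
  targets <- unique(setdiff(targets, regulator))
  targets <- intersect(targets, rownames(m))
  if (!length(targets)) {
    warning("no predicted targets present in the matrix")
    return(list(regulator = regulator, c = c_val, m = 0, n = 0L, score = 0,
                regulated = character(0)))
  }
  mis <- vapply(targets, function(g) mutual_info(m[g, ], pseudotime, bins),
                numeric(1))
  regulated <- vapply(targets, function(g) {
    null <- vapply(seq_len(n_perm), function(i)
      mutual_info(m[g, ], sample(pseudotime), bins), numeric(1))
    mis[[g]] > stats::quantile(null, quantile)
  }, logical(1))
  n <- sum(regulated)
  m_val <- mean(mis)
  list(regulator = regulator, c = c_val, m = m_val, n = as.integer(n),
       score = c_val * m_val * n, regulated = targets[regulated])
}

#' Lineage-coordinated transcription factors
#'
#' TFs whose expression changes significantly along the trajectory:
#' Spearman correlation with pseudotime, Benjamini-Hochberg FDR across the
#' TF list, retain FDR < `fdr`.
#'
#' @inheritParams grn_score
#' @param tf_list candidate TF gene ids.
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame (tf, rho, p, fdr, coordinated) with the retained TFs
#'   flagged.
#' @export
lineage_tfs <- function(x, tf_list, pseudotime, fdr = 0.05) {
  m <- as_gene_matrix(x)
  tf_list <- intersect(unique(tf_list), rownames(m))
  if (!length(tf_list)) stop("no TFs present in the matrix")
  res <- lapply(tf_list, function(g) {
    v <- m[g, ]
    if (stats::sd(v) == 0) return(c(rho = 0, p = 1))
    ct <- suppressWarnings(stats::cor.test(v, pseudotime, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- data.frame(tf = tf_list,
                    rho = vapply(res, `[[`, numeric(1), "rho"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$coordinated <- out$fdr < fdr
  out
}

#' Lineage-coordinated TF co-expression network
#'
#' Builds the co-expression graph over coordinated TFs: an edge joins two
#' TFs whose Pearson correlation across trajectory cells exceeds
#' `r_threshold`; a TF stays in the network only while it keeps at least
#' `min_degree` such neighbours, applied iteratively to a fixed point
#' (removing one node can drop a neighbour below the bar).
#'
#' @inheritParams grn_score
#' @param tfs coordinated TF gene ids.
#' @param r_threshold Pearson correlation threshold (edges require
#'   r > threshold; default 0.1).
#' @param min_degree minimum retained degree (default 5).
#' @return list with `nodes` (data.frame: tf, degree, mean_expression),
#'   `edges` (data.frame: tf_a, tf_b, r), and `r` (the correlation matrix
#'   over the input TFs).
#' @export
build_tf_network <- function(x, tfs, r_threshold = 0.1, min_degree = 5L) {
  m <- as_gene_matrix(x)
  tfs <- intersect(unique(tfs), rownames(m))
  if (length(tfs) <= min_degree)
    warning("fewer than min_degree + 1 TFs: network will be empty")
  expr <- t(as.matrix(m[tfs, , drop = FALSE]))
  keep_var <- apply(expr, 2, stats::sd) > 0
  r <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  if (sum(keep_var) >= 2)
    r[keep_var, keep_var] <- stats::cor(expr[, keep_var, drop = FALSE])
  adj <- r > r_threshold
  diag(adj) <- FALSE
  keep <- prune_min_degree(adj, min_degree)
  nodes <- tfs[keep]
  if (!length(nodes)) {
    warning("no TF reaches the degree threshold; empty network")
    return(list(nodes = data.frame(tf = character(0), degree = integer(0),
                                   mean_expression = numeric(0)),
                edges = data.frame(tf_a = character(0), tf_b = character(0),
                                   r = numeric(0)),
                r = r))
  }
  sub <- adj[nodes, nodes, drop = FALSE]
  deg <- rowSums(sub)
  ij <- which(sub & upper.tri(sub), arr.ind = TRUE)
  edges <- data.frame(tf_a = nodes[ij[, 1]], tf_b = nodes[ij[, 2]],
                      r = r[nodes, nodes][ij], stringsAsFactors = FALSE)
  list(nodes = data.frame(tf = nodes, degree = as.integer(deg),
                          mean_expression = colMeans(expr[, nodes, drop = FALSE]),
                          stringsAsFactors = FALSE),
       edges = edges, r = r)
}

# iterative minimum-degree pruning; the fixed point is unique because
# removing nodes only ever lowers degrees (monotone), so the surviving set
# is the maximal subgraph with min degree >= k regardless of removal order
prune_min_degree <- function(adj, k) {
  keep <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE])
    drop <- keep & deg < k
    if (!any(drop)) break
    keep[drop] <- FALSE
    if (!any(keep)) break
  }
  keep
}

as_gene_matrix <- function(x) {
  if (inherits(x, "expr_matrix")) {
    if (is.null(x$normalized)) stop("normalized layer absent")
    return(x$normalized)
  }
  if (is.null(rownames(x))) stop("matrix must have gene rownames")
  x
}
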