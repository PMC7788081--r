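#' Pseudobulk profile of a random cell sample
#'
#' Mean normalized expression over `size` cells drawn from the given
#' population. Sampling is without replacement when the population has at
#' least `size` cells, with replacement otherwise.
#'
#' @param x a normalized `expr_matrix`.
#' @param cells barcodes of the population.
#' @param size number of cells to draw (default 30).
#' @param genes optional gene ids to restrict the profile to.
#' @return named numeric vector (one entry per gene) with attributes
#'   `population_size` and `replace`.
#' @export
pseudobulk <- function(x, cells, size = 30L, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$normalized)) stop("normalized layer absent; run normalize_umi()")
  if (!length(cells)) stop("empty population")
  replace <- length(cells) < size
  take <- cells[sample.int(length(cells), size, replace = replace)]
  m <- x$normalized[, take, drop = FALSE]
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  p <- Matrix::rowMeans(m)
  attr(p, "population_size") <- length(cells)
  attr(p, "replace") <- replace
  p
}

#' Pairwise pseudobulk statistics
#'
#' The four per-pair measurement channels feeding the composite index:
#' `stat_euclidean` (Euclidean distance of expression), `stat_spearman`
#' (Spearman rank correlation), `stat_pc_dist` (Euclidean distance in a
#' principal-component embedding, each component weighted by its
#' explained-variance fraction) and `stat_gsea_profile` (Euclidean distance
#' between the vectors of normalized recovery-curve AUCs over a gene-set
#' collection).
#'
#' @param p,q pseudobulk profiles over the same genes (named numeric).
#' @param genes optional gene ids to restrict to; default intersection
#'   checked for equality.
#' @return a single numeric value. Distances are >= 0; Spearman is in
#'   \[-1, 1\].
#' @export
stat_euclidean <- function(p, q, genes = NULL) {
  v <- align_profiles(p, q, genes)
  sqrt(sum((v$p - v$q)^2))
}

#' @rdname stat_euclidean
#' @export
stat_spearman <- function(p, q, genes = NULL) {
  v <- align_profiles(p, q, genes)
  if (length(v$p) < 3) stop("need at least 3 genes for Spearman correlation")
  if (stats::sd(v$p) == 0 || stats::sd(v$q) == 0)
    stop("constant profile: Spearman correlation undefined")
  stats::cor(v$p, v$q, method = "spearman")
}

#' @rdname stat_euclidean
#' @param basis a `pca_basis` from [fit_pca_basis()].
#' @export
stat_pc_dist <- function(p, q, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  v <- align_profiles(p, q, basis$genes)
  dp <- (v$p - basis$center) %*% basis$rotation
  dq <- (v$q - basis$center) %*% basis$rotation
  sqrt(sum(basis$weights * (dp - dq)^2))
}

#' @rdname stat_euclidean
#' @param sets gene-set collection (named list of gene ids).
#' @param L recovery-curve window (default 5000 ranks).
#' @export
stat_gsea_profile <- function(p, q, sets, L = 5000L) {
  v <- align_profiles(p, q, NULL)
  ap <- vapply(sets, function(s) recovery_auc(rank_genes(v$p), s, L)$norm_auc,
               numeric(1))
  aq <- vapply(sets, function(s) recovery_auc(rank_genes(v$q), s, L)$norm_auc,
               numeric(1))
  sqrt(sum((ap - aq)^2))
}

align_profiles <- function(p, q, genes) {
  if (is.null(names(p)) || is.null(names(q))) stop("profiles must be named by gene")
  if (is.null(genes)) {
    if (!identical(names(p), names(q))) stop("profiles cover different genes")
    genes <- names(p)
  }
  if (!length(genes)) stop("empty gene list")
  if (!all(genes %in% names(p)) || !all(genes %in% names(q)))
    stop("profiles do not cover the requested genes")
  list(p = p[genes], q = q[genes])
}

#' Orientation of a measurement channel
#'
#' @param statistic one of `"euclidean"`, `"spearman"`, `"pc_dist"`,
#'   `"gsea_profile"`.
#' @return `"distance"` or `"similarity"`.
#' @export
stat_orientation <- function(statistic) {
  switch(match.arg(statistic, c("euclidean", "spearman", "pc_dist",
                                "gsea_profile")),
         spearman = "similarity", "distance")
}

#' Fit a principal-component basis on the joint normalized matrix
#'
#' The basis is fitted once on all cells (reference and query together) over
#' a fixed gene space, so query profiles project without out-of-sample
#' mapping. Component weights are explained-variance fractions relative to
#' total variance.
#'
#' @param mats list of normalized `expr_matrix` objects (or one).
#' @param genes gene ids defining the space.
#' @param n_pc number of components (default 30).
#' @return object of class `pca_basis`: `rotation` (genes x n_pc), `center`,
#'   `weights` (explained-variance fractions), `genes`.
#' @export
fit_pca_basis <- function(mats, genes, n_pc = 30L) {
  if (inherits(mats, "expr_matrix")) mats <- list(mats)
  blocks <- lapply(mats, function(m) {
    if (is.null(m$normalized)) stop("normalized layer absent")
    t(as.matrix(m$normalized[genes, , drop = FALSE]))
  })
  X <- do.call(rbind, blocks)
  n_pc <- min(n_pc, ncol(X), nrow(X) - 1L)
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pc)
  ev <- fit$sdev^2
  structure(list(rotation = fit$rotation,
                 center = fit$center,
                 weights = ev[seq_len(n_pc)] / sum(ev),
                 genes = genes),
            class = "pca_basis")
}

#' Empirical null distribution of a pairwise statistic
#'
#' Repeatedly (default 10,000 times) draws fresh pseudobulk profiles from
#' both populations and records the statistic, yielding the pair's
#' resampling distribution; its median is the pair's measurement score.
#'
#' @param x a normalized `expr_matrix` holding both populations (or use
#'   `x_query` for a separate query matrix).
#' @param labels labeling data.frame (`barcode`, `population`).
#' @param query_pop,ref_pop population names.
#' @param statistic one of `"euclidean"`, `"spearman"`, `"pc_dist"`,
#'   `"gsea_profile"`.
#' @param n_resamples number of resampling iterations (default 10000).
#' @param size pseudobulk sample size (default 30).
#' @param genes gene ids defining the comparison space (sorted internally so
#'   ranking tie-breaks are deterministic); default all genes of `x`.
#' @param basis `pca_basis`, required for `pc_dist`.
#' @param sets gene-set collection, required for `gsea_profile`.
#' @param L recovery-curve window for `gsea_profile`.
#' @param x_query optional separate `expr_matrix` for the query population.
#' @param query_labels labeling for `x_query` (defaults to `labels`).
#' @param seed optional integer seed (set once before drawing).
#' @return object of class `empirical_null`: `values`, `median`,
#'   `orientation`, `statistic`, `query`, `reference`.
#' @export
build_null <- function(x, labels, query_pop, ref_pop, statistic,
                       n_resamples = 10000L, size = 30L, genes = NULL,
                       basis = NULL, sets = NULL, L = 5000L,
                       x_query = NULL, query_labels = NULL, seed = NULL) {
  statistic <- match.arg(statistic, c("euclidean", "spearman", "pc_dist",
                                      "gsea_profile"))
  if (n_resamples < 2) stop("n_resamples must be at least 2")
  if (n_resamples < 100) warning("n_resamples < 100 gives an unstable null")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x_query)) x_query <- x
  if (is.null(query_labels)) query_labels <- labels
  if (is.null(genes)) genes <- rownames(x$counts)
  genes <- sort(genes)
  Xq <- dense_cells_by_genes(x_query, pop_cells(x_query, query_labels, query_pop), genes)
  Xr <- dense_cells_by_genes(x, pop_cells(x, labels, ref_pop), genes)
  vals <- null_values(Xq, Xr, statistic, n_resamples, size,
                      basis = basis, sets = sets, L = L, genes = genes)
  structure(list(values = vals, median = stats::median(vals),
                 orientation = stat_orientation(statistic),
                 statistic = statistic, query = query_pop,
                 reference = ref_pop, n_resamples = n_resamples,
                 size = size),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("empirical_null: %s(%s, %s), %d resamples, median %.4g (%s)\n",
              x$statistic, x$query, x$reference, x$n_resamples, x$median,
              x$orientation))
  invisible(x)
}

dense_cells_by_genes <- function(x, cells, genes) {
  if (is.null(x$normalized)) stop("normalized layer absent; run normalize_umi()")
  if (!all(genes %in% rownames(x$normalized)))
    stop("gene space not covered by matrix")
  t(as.matrix(x$normalized[genes, cells, drop = FALSE]))
}

draw_index_matrix <- function(n_cells, n_resamples, size) {
  replace <- n_cells < size
  t(vapply(seq_len(n_resamples),
           function(i) sample.int(n_cells, size, replace = replace),
           integer(size)))
}

# shared resampling engine: returns n_resamples statistic values from
# cells-by-genes dense matrices for the two populations
null_values <- function(Xq, Xr, statistic, n_resamples, size,
                        basis = NULL, sets = NULL, L = 5000L, genes = NULL) {
  idxq <- draw_index_matrix(nrow(Xq), n_resamples, size)
  idxr <- draw_index_matrix(nrow(Xr), n_resamples, size)
  P <- .profile_means_cpp(Xq, idxq)
  Q <- .profile_means_cpp(Xr, idxr)
  switch(statistic,
    euclidean = sqrt(rowSums((P - Q)^2)),
    spearman = .spearman_rows_cpp(P, Q),
    pc_dist = {
      if (is.null(basis)) stop("pc_dist requires a pca_basis")
      if (!identical(basis$genes, genes))
        stop("basis gene space does not match the comparison gene space")
      dp <- sweep(P, 2, basis$center) %*% basis$rotation
      dq <- sweep(Q, 2, basis$center) %*% basis$rotation
      sqrt(as.vector((dp - dq)^2 %*% basis$weights))
    },
    gsea_profile = {
      if (is.null(sets) || !length(sets)) stop("gsea_profile requires gene sets")
      sidx <- lapply(sets, function(s) {
        i <- match(intersect(s, genes), genes)
        as.integer(i)
      })
      keep <- lengths(sidx) > 0
      if (!any(keep)) stop("no gene set overlaps the gene space")
      A <- .auc_rows_cpp(P, sidx[keep], as.integer(L))
      B <- .auc_rows_cpp(Q, sidx[keep], as.integer(L))
      sqrt(rowSums((A - B)^2))
    })
}
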