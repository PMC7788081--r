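#' Rank genes of a profile by decreasing expression
#'
#' Ties are broken by gene id so the ranking — and everything downstream of
#' it — is deterministic.
#'
#' @param profile named numeric vector (gene -> expression).
#' @return character vector of gene ids, most expressed first.
#' @export
rank_genes <- function(profile) {
  if (!length(profile)) stop("empty profile")
  if (is.null(names(profile))) stop("profile must be named by gene")
  names(profile)[order(-profile, names(profile), method = "radix")]
}

#' Recovery-curve area under the curve for one gene set
#'
#' Walking down the ranked gene list, the recovery curve steps up each time
#' a set member is encountered; the raw AUC is the sum of the cumulative hit
#' count over the first `L` ranks. The normalized AUC divides by the
#' top-packed maximum (all members occupying the top ranks), so scores are
#' comparable across set sizes: 1 when every reachable member sits at the
#' top of the list, 0 when no member appears in the window.
#'
#' @param ranked character vector of gene ids, best rank first.
#' @param gene_set character vector of member gene ids.
#' @param L window: number of top ranks integrated (default 5000; may
#'   exceed the list length, past which the curve is flat).
#' @return list with `raw_auc`, `norm_auc`, `n_hits` (members inside the
#'   window), `L`.
#' @export
recovery_auc <- function(ranked, gene_set, L = 5000L) {
  if (L < 1) stop("L must be >= 1")
  if (!length(gene_set)) stop("empty gene set")
  gene_set <- unique(gene_set)
  r <- match(gene_set, ranked)
  r <- r[!is.na(r)]
  if (!length(r))
    warning("gene set disjoint from the ranked gene universe")
  m <- min(length(r), L)
  hit_r <- r[r <= L]
  raw <- sum(L - hit_r + 1)
  denom <- m * (m + 1) / 2 + m * (L - m)
  list(raw_auc = raw,
       norm_auc = if (denom > 0) raw / denom else 0,
       n_hits = length(hit_r), L = as.integer(L))
}

#' Resampled AUC distribution of a gene set in one population
#'
#' Repeatedly draws a pseudobulk profile (default 30 cells), ranks genes,
#' and records the normalized recovery AUC of the set.
#'
#' @param x normalized `expr_matrix`.
#' @param cells barcodes of the population.
#' @param gene_set member gene ids.
#' @param n number of samplings (default 10000).
#' @param size pseudobulk size (default 30).
#' @param L recovery window.
#' @param seed optional integer seed.
#' @return numeric vector of length `n` of normalized AUCs.
#' @export
auc_distribution <- function(x, cells, gene_set, n = 10000L, size = 30L,
                             L = 5000L, seed = NULL) {
  if (!length(cells)) stop("empty population")
  if (!is.null(seed)) set.seed(seed)
  genes <- sort(rownames(x$normalized))
  X <- dense_cells_by_genes(x, cells, genes)
  idx <- draw_index_matrix(nrow(X), n, size)
  P <- .profile_means_cpp(X, idx)
  si <- match(intersect(unique(gene_set), genes), genes)
  if (!length(si)) {
    warning("gene set disjoint from the gene universe")
    return(numeric(n))
  }
  as.vector(.auc_rows_cpp(P, list(as.integer(si)), as.integer(L)))
}

#' Z-score contrast of gene-set enrichment between two cell populations
#'
#' Builds resampled AUC distributions for populations A and B and reports
#' `z = (mean(AUC_A) - mean(AUC_B)) / sd(AUC_B)`: the enrichment of the set
#' in A relative to B's resampling distribution. Positive z means the
#' pathway is up in A.
#'
#' @param x normalized `expr_matrix`.
#' @param labels labeling data.frame (`barcode`, `population`).
#' @param pop_a,pop_b population names.
#' @param gene_set member gene ids.
#' @inheritParams auc_distribution
#' @return list with `z`, `mean_a`, `mean_b`, `sd_b`, `n`.
#' @export
enrichment_z <- function(x, labels, pop_a, pop_b, gene_set, n = 10000L,
                         size = 30L, L = 5000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  auc_a <- auc_distribution(x, pop_cells(x, labels, pop_a), gene_set,
                            n = n, size = size, L = L)
  auc_b <- auc_distribution(x, pop_cells(x, labels, pop_b), gene_set,
                            n = n, size = size, L = L)
  z_from_auc(auc_a, auc_b)
}

#' @rdname enrichment_z
#' @param auc_a,auc_b resampled AUC distributions (numeric vectors).
#' @export
z_from_auc <- function(auc_a, auc_b) {
  s <- stats::sd(auc_b)
  if (!is.finite(s) || s == 0)
    stop("reference AUC distribution has zero spread; increase n or check ",
         "for a degenerate population")
  list(z = (mean(auc_a) - mean(auc_b)) / s,
       mean_a = mean(auc_a), mean_b = mean(auc_b), sd_b = s,
       n = length(auc_a))
}
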