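#' Per-channel likelihoods from empirical nulls
#'
#' For one measurement channel, converts per-reference scores (null medians)
#' into likelihood values via the best-candidate tail probability: with
#' distance-oriented channels the benchmark `S*` is the smallest median
#' across references and the likelihood of reference j is the fraction of
#' j's null at or below `S*`; for similarity channels the benchmark is the
#' largest median and the tail runs upward. The best reference thus scores
#' about 0.5 (its own median splits its null) while references whose whole
#' null is worse than the benchmark drop to the floor `eps`. The tail
#' probability is scale-free, so channels with different units are
#' comparable.
#'
#' @param nulls list of `empirical_null` objects, one per candidate
#'   reference, all for the same statistic and query.
#' @param eps likelihood floor preventing one channel from zeroing the
#'   composite product (default 1e-6).
#' @return named numeric vector of likelihoods over references.
#' @export
channel_likelihood <- function(nulls, eps = 1e-6) {
  if (!length(nulls)) stop("no empirical nulls supplied")
  stats_ <- unique(vapply(nulls, function(z) z$statistic, character(1)))
  if (length(stats_) != 1)
    stop("mixed statistics in one channel: ", paste(stats_, collapse = ", "))
  if (any(vapply(nulls, function(z) !length(z$values), logical(1))))
    stop("empty null distribution")
  medians <- vapply(nulls, function(z) z$median, numeric(1))
  orientation <- nulls[[1]]$orientation
  if (orientation == "distance") {
    s_star <- min(medians)
    L <- vapply(nulls, function(z) mean(z$values <= s_star), numeric(1))
  } else {
    s_star <- max(medians)
    L <- vapply(nulls, function(z) mean(z$values >= s_star), numeric(1))
  }
  L <- pmax(L, eps)
  names(L) <- vapply(nulls, function(z) z$reference, character(1))
  L
}

#' Composite posterior over reference populations
#'
#' Each channel's likelihoods are combined with the prior into a
#' per-channel posterior, and the composite index is the product of the
#' per-channel posteriors over the measurements, renormalized over
#' references.
#'
#' @param likelihoods named list (one element per channel) of named numeric
#'   likelihood vectors over the same references.
#' @param priors prior over references (named, sums to 1); default uniform.
#' @return list with `posterior` (matrix channels x references, rows sum to
#'   1), `combined` (named vector over references summing to 1), `priors`.
#' @export
cci_posterior <- function(likelihoods, priors = NULL) {
  if (!length(likelihoods)) stop("need at least one measurement channel")
  refs <- names(likelihoods[[1]])
  if (is.null(refs)) stop("likelihood vectors must be named by reference")
  for (L in likelihoods)
    if (!identical(sort(names(L)), sort(refs)))
      stop("channels cover different reference sets")
  if (is.null(priors))
    priors <- stats::setNames(rep(1 / length(refs), length(refs)), refs)
  if (abs(sum(priors) - 1) > 1e-6) stop("priors must sum to 1")
  priors <- priors[refs]
  post <- t(vapply(names(likelihoods), function(ch) {
    w <- likelihoods[[ch]][refs] * priors
    s <- sum(w)
    if (!is.finite(s) || s <= 0)
      stop("channel ", ch, " has non-normalizable likelihoods")
    w / s
  }, numeric(length(refs))))
  rownames(post) <- names(likelihoods)
  colnames(post) <- refs
  comb <- apply(post, 2, prod)
  comb <- comb / sum(comb)
  list(posterior = post, combined = comb, priors = priors)
}

#' Assign each query population its reference counterpart
#'
#' The counterpart is the argmax of the combined composite posterior; the
#' assigned label is the counterpart name with the `-L` suffix. Exact ties
#' are broken toward the reference closest to the tree root (the
#' conservative, root-ward stemness call), then lexicographically.
#'
#' @param posteriors named list (query population -> result of
#'   [cci_posterior()]).
#' @param tree optional `pop_tree` for the root-ward tie-break.
#' @param flag_margin assignments whose margin over the runner-up falls
#'   below this are flagged (default 0.1).
#' @return data.frame: query, counterpart, label, posterior, margin,
#'   flagged.
#' @export
assign_counterparts <- function(posteriors, tree = NULL, flag_margin = 0.1) {
  depths <- if (!is.null(tree)) tree_depths(tree) else NULL
  rows <- lapply(names(posteriors), function(qp) {
    comb <- posteriors[[qp]]$combined
    best <- max(comb)
    cand <- names(comb)[comb == best]
    if (length(cand) > 1) {
      if (!is.null(depths) && all(cand %in% names(depths)))
        cand <- cand[depths[cand] == min(depths[cand])]
      cand <- sort(cand)
    }
    pick <- cand[1]
    runner <- if (length(comb) > 1) max(comb[names(comb) != pick]) else 0
    data.frame(query = qp, counterpart = pick,
               label = paste0(pick, "-L"),
               posterior = unname(best),
               margin = unname(best - runner),
               flagged = unname(best - runner) < flag_margin,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map query cell populations onto a reference atlas
#'
#' The main fitting function. For every (query population, reference
#' population) pair and every measurement channel it builds the empirical
#' resampling distribution of the pairwise statistic (fresh pseudobulk
#' pairs each iteration), converts the per-reference medians into
#' best-candidate tail likelihoods, combines the channels into a composite
#' posterior, and assigns each query population the reference counterpart
#' maximizing it.
#'
#' @param reference normalized `expr_matrix` of the reference atlas.
#' @param ref_labels labeling of the reference (`barcode`, `population`).
#' @param query normalized `expr_matrix` of the query cells.
#' @param query_labels labeling of the query populations.
#' @param gene_sets gene-set collection for the enrichment-profile channel
#'   (required unless that channel is dropped).
#' @param tree optional `pop_tree` over the reference populations.
#' @param channels measurement channels to combine (default all four).
#' @param n_resamples resampling iterations per pair (default 10000).
#' @param size pseudobulk sample size (default 30).
#' @param n_hvg highly variable genes per dataset; the comparison space is
#'   the union of both HVG sets intersected with genes detected in both
#'   datasets (default 2000).
#' @param n_pc principal components for the embedding channel (default 30).
#' @param L recovery-curve window for the enrichment channel (default 5000).
#' @param priors optional named prior over reference populations.
#' @param eps likelihood floor (default 1e-6).
#' @param keep_nulls keep the full resampling distributions in the fit
#'   (default FALSE: only medians are kept).
#' @param seed integer seed governing all resampling.
#' @return object of class `cci`; see [print.cci()], [summary.cci()],
#'   [coef.cci()], [plot.cci()], [mapping_report()].
#' @export
cci <- function(reference, ref_labels, query, query_labels,
                gene_sets = NULL, tree = NULL,
                channels = c("euclidean", "spearman", "pc_dist",
                             "gsea_profile"),
                n_resamples = 10000L, size = 30L, n_hvg = 2000L,
                n_pc = 30L, L = 5000L, priors = NULL, eps = 1e-6,
                keep_nulls = FALSE, seed = 1L) {
  channels <- match.arg(channels, several.ok = TRUE)
  if ("gsea_profile" %in% channels && is.null(gene_sets))
    stop("the gsea_profile channel requires gene_sets (or drop the channel)")
  if (is.null(reference$normalized) || is.null(query$normalized))
    stop("normalized layer absent; run normalize_umi() on both matrices")
  set.seed(seed)

  ref_pops <- sort(unique(ref_labels$population))
  query_pops <- sort(unique(query_labels$population))
  if (!is.null(tree)) {
    out <- setdiff(ref_pops, tree$nodes)
    if (length(out)) stop("reference populations absent from tree: ",
                          paste(out, collapse = ", "))
  }

  detected_ref <- rownames(reference$counts)[Matrix::rowSums(reference$counts) > 0]
  detected_query <- rownames(query$counts)[Matrix::rowSums(query$counts) > 0]
  hvg <- union(select_hvg(reference, n_hvg), select_hvg(query, n_hvg))
  genes <- sort(intersect(hvg, intersect(detected_ref, detected_query)))
  if (length(genes) < 3) stop("shared gene space too small")

  basis <- if ("pc_dist" %in% channels)
    fit_pca_basis(list(reference, query), genes, n_pc = n_pc) else NULL

  Xr <- lapply(ref_pops, function(p)
    dense_cells_by_genes(reference, pop_cells(reference, ref_labels, p), genes))
  names(Xr) <- ref_pops
  Xq <- lapply(query_pops, function(p)
    dense_cells_by_genes(query, pop_cells(query, query_labels, p), genes))
  names(Xq) <- query_pops

  sidx <- NULL
  if ("gsea_profile" %in% channels) {
    sidx <- lapply(gene_sets, function(s) as.integer(match(intersect(s, genes), genes)))
    sidx <- sidx[lengths(sidx) > 0]
    if (!length(sidx)) stop("no gene set overlaps the comparison gene space")
  }

  scores <- list()
  posteriors <- list()
  likelihoods <- list()
  nulls_kept <- if (keep_nulls) list() else NULL
  for (qp in query_pops) {
    nulls_q <- list()
    for (ch in channels) {
      nulls_q[[ch]] <- lapply(ref_pops, function(rp) {
        vals <- null_values(Xq[[qp]], Xr[[rp]], ch, n_resamples, size,
                            basis = basis, sets = gene_sets, L = L,
                            genes = genes)
        structure(list(values = vals, median = stats::median(vals),
                       orientation = stat_orientation(ch), statistic = ch,
                       query = qp, reference = rp,
                       n_resamples = n_resamples, size = size),
                  class = "empirical_null")
      })
      names(nulls_q[[ch]]) <- ref_pops
    }
    lik <- lapply(nulls_q, channel_likelihood, eps = eps)
    likelihoods[[qp]] <- lik
    posteriors[[qp]] <- cci_posterior(lik, priors)
    scores[[qp]] <- vapply(nulls_q, function(chn)
      vapply(chn, function(z) z$median, numeric(1)),
      numeric(length(ref_pops)))
    if (keep_nulls) nulls_kept[[qp]] <- nulls_q
  }

  assignments <- assign_counterparts(posteriors, tree = tree)
  structure(list(assignments = assignments, posteriors = posteriors,
                 likelihoods = likelihoods,
                 scores = scores, channels = channels, genes = genes,
                 basis = basis, tree = tree, nulls = nulls_kept,
                 n_resamples = n_resamples, size = size, seed = seed,
                 ref_pops = ref_pops, query_pops = query_pops,
                 call = match.call()),
            class = "cci")
}

#' @export
print.cci <- function(x, ...) {
  cat("Counterpart composite index fit\n")
  cat(sprintf("  %d query population(s) against %d reference population(s)\n",
              length(x$query_pops), length(x$ref_pops)))
  cat(sprintf("  channels: %s; %d resamples of %d-cell pseudobulks; %d genes\n",
              paste(x$channels, collapse = ", "), x$n_resamples, x$size,
              length(x$genes)))
  cat("\nAssignments:\n")
  print(x$assignments, row.names = FALSE)
  invisible(x)
}

#' Combined posterior matrix of a fit
#' @param object a `cci` fit.
#' @param ... unused.
#' @return matrix (query populations x reference populations), rows sum
#'   to 1.
#' @export
coef.cci <- function(object, ...) {
  t(vapply(object$query_pops,
           function(qp) object$posteriors[[qp]]$combined[object$ref_pops],
           numeric(length(object$ref_pops))))
}

#' @export
summary.cci <- function(object, ...) {
  structure(list(assignments = object$assignments,
                 combined = coef(object),
                 channels = object$channels,
                 n_resamples = object$n_resamples,
                 n_genes = length(object$genes)),
            class = "summary.cci")
}

#' @export
print.summary.cci <- function(x, ...) {
  cat("Combined composite posterior (rows = query populations):\n")
  print(round(x$combined, 4))
  cat("\nAssignments:\n")
  print(x$assignments, row.names = FALSE)
  invisible(x)
}

#' Posterior heatmap of a fit
#'
#' Base-graphics image of the combined posterior, queries in rows.
#'
#' @param x a `cci` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.cci <- function(x, ...) {
  m <- coef(x)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "reference population",
                  ylab = "query population",
                  main = "Combined composite posterior", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 1, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}

#' Heterogeneity and stemness readouts of a mapping
#'
#' Summarizes a fit's assignments on the reference tree: heterogeneity is
#' the number of distinct counterparts and the largest pairwise tree
#' distance among them (the spread of the mapped populations on the
#' lineage tree); stemness is the minimum root distance among the
#' counterparts (smaller = closer to the stem compartment). When per-cell
#' labels are supplied, per-sample query-population abundances are included.
#'
#' @param fit a `cci` fit (with a tree) or an assignment data.frame.
#' @param tree `pop_tree`; taken from the fit when omitted.
#' @param query_labels optional labeling with `sample` column for
#'   abundances.
#' @return list with `per_sample` (data.frame: sample, n_counterparts,
#'   tree_span, stemness_depth) and `abundances` (data.frame or NULL).
#' @export
mapping_report <- function(fit, tree = NULL, query_labels = NULL) {
  asg <- if (inherits(fit, "cci")) fit$assignments else fit
  if (is.null(tree) && inherits(fit, "cci")) tree <- fit$tree
  if (is.null(tree)) stop("mapping_report requires a population tree")
  missing <- setdiff(asg$counterpart, tree$nodes)
  if (length(missing))
    stop("counterpart absent from tree: ", paste(missing, collapse = ", "))
  depths <- tree_depths(tree)
  dists <- tree_distances(tree)
  samples <- if (!is.null(query_labels) && "sample" %in% names(query_labels)) {
    split(asg, vapply(asg$query, function(q) {
      s <- unique(query_labels$sample[query_labels$population == q])
      if (length(s) != 1) "all" else as.character(s)
    }, character(1)))
  } else list(all = asg)
  per_sample <- do.call(rbind, lapply(names(samples), function(sm) {
    cp <- unique(samples[[sm]]$counterpart)
    span <- if (length(cp) > 1) max(dists[cp, cp]) else 0
    data.frame(sample = sm, n_counterparts = length(cp),
               tree_span = as.numeric(span),
               stemness_depth = as.numeric(min(depths[cp])),
               stringsAsFactors = FALSE)
  }))
  abund <- NULL
  if (!is.null(query_labels)) {
    smp <- if ("sample" %in% names(query_labels)) query_labels$sample
           else rep("all", nrow(query_labels))
    tab <- table(smp, query_labels$population)
    abund <- as.data.frame(prop.table(tab, 1), stringsAsFactors = FALSE)
    names(abund) <- c("sample", "query", "abundance")
    abund$label <- asg$label[match(abund$query, asg$query)]
  }
  list(per_sample = per_sample, abundances = abund)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
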