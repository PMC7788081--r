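#' Shannon entropy of a single cell's transcriptome
#'
#' `-sum p_i log2 p_i` over the cell's expressed genes, with
#' `p_i = count_i / total`. Raw UMI proportions are used so the measure is
#' self-contained per cell; it is invariant to scaling all counts by a
#' constant and bounded by `log2(number of expressed genes)`, attained at
#' uniformity.
#'
#' @param counts per-gene counts for one cell (non-negative).
#' @return list with `entropy` (bits) and `n_expressed_genes`.
#' @export
cell_entropy <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total == 0) stop("all-zero cell; run apply_qc() first")
  p <- counts[counts > 0] / total
  list(entropy = -sum(p * log2(p)), n_expressed_genes = length(p))
}

#' Per-cell entropy table for an expression matrix
#'
#' @param x an `expr_matrix` (entropy is computed on the raw counts).
#' @return data.frame: barcode, entropy_bits, n_expressed_genes.
#' @export
cell_entropies <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$counts
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) stop("all-zero cells present; run apply_qc() first")
  # -sum p log2 p = log2(total) - sum(c * log2 c)/total, over nonzeros
  clog <- m
  clog@x <- m@x * log2(m@x)
  ent <- log2(tot) - Matrix::colSums(clog) / tot
  data.frame(barcode = colnames(m),
             entropy_bits = as.numeric(ent),
             n_expressed_genes = as.integer(Matrix::colSums(m > 0)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Population entropy summary
#'
#' Median and interquartile range of per-cell entropy per population, for
#' cross-population potency comparisons.
#'
#' @param x an `expr_matrix`.
#' @param labels labeling data.frame (`barcode`, `population`).
#' @return data.frame: population, n_cells, median_entropy, iqr_entropy.
#' @export
entropy_summary <- function(x, labels) {
  ent <- cell_entropies(x)
  ent$population <- labels$population[match(ent$barcode, labels$barcode)]
  ent <- ent[!is.na(ent$population), ]
  do.call(rbind, lapply(split(ent, ent$population), function(d)
    data.frame(population = d$population[1], n_cells = nrow(d),
               median_entropy = stats::median(d$entropy_bits),
               iqr_entropy = stats::IQR(d$entropy_bits),
               stringsAsFactors = FALSE)))
}
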