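#' Construct an expression matrix object
#'
#' Container for a cell-by-gene UMI count matrix. Counts are stored
#' genes-in-rows, cells-in-columns (the single-cell convention) as a sparse
#' `dgCMatrix`. A `normalized` layer is added by [normalize_umi()].
#'
#' @param counts matrix or sparse Matrix of non-negative integer UMI counts,
#'   genes x cells, with unique rownames (gene ids) and colnames (barcodes).
#' @param gene_names optional character vector of display names (e.g. HGNC
#'   symbols) used for mitochondrial-gene detection; defaults to rownames.
#' @param mito_prefix prefix identifying mitochondrial genes
#'   (case-insensitive match against `gene_names`).
#' @return an object of class `expr_matrix` with elements `counts`
#'   (dgCMatrix), `normalized` (NULL until [normalize_umi()]), `gene_names`,
#'   and `mito` (logical per gene).
#' @export
expr_matrix <- function(counts, gene_names = NULL, mito_prefix = "MT-") {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell barcode colnames")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell barcodes: ",
         paste(utils::head(unique(colnames(counts)[duplicated(colnames(counts))]), 3),
               collapse = ", "))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  if (is.null(gene_names)) gene_names <- rownames(counts)
  stopifnot(length(gene_names) == nrow(counts))
  mito <- grepl(paste0("^", mito_prefix), gene_names, ignore.case = TRUE)
  structure(list(counts = counts, normalized = NULL,
                 gene_names = gene_names, mito = mito),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells (%s normalized layer, %d mito genes)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "no" else "with", sum(x$mito)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Subset an expression matrix by genes and/or cells
#' @param x an `expr_matrix`
#' @param genes,cells indices, names or logical vectors; NULL keeps all.
#' @return an `expr_matrix` with both layers subset consistently.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  if (is.character(gi)) gi <- match(gi, rownames(x$counts))
  out <- x
  out$counts <- x$counts[gi, ci, drop = FALSE]
  if (!is.null(x$normalized)) out$normalized <- x$normalized[gi, ci, drop = FALSE]
  out$gene_names <- x$gene_names[if (is.logical(gi)) which(gi) else gi]
  out$mito <- x$mito[if (is.logical(gi)) which(gi) else gi]
  out
}

#' Read a UMI count matrix
#'
#' Reads either a 10x-style triplet directory (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`/`genes.tsv`, optionally gzipped) or a dense delimited table
#' (header row = cell barcodes, first column = gene ids; the transposed
#' layout with genes in columns is accepted via `transpose = TRUE`).
#'
#' @param path directory (triplet) or file (dense TSV/CSV).
#' @param mito_prefix passed to [expr_matrix()].
#' @param transpose for dense tables, set TRUE when rows are cells.
#' @return an `expr_matrix`.
#' @export
read_counts <- function(path, mito_prefix = "MT-", transpose = FALSE) {
  if (dir.exists(path)) {
    find1 <- function(stem) {
      cand <- file.path(path, c(stem, paste0(stem, ".gz")))
      cand <- cand[file.exists(cand)]
      if (!length(cand)) stop("missing ", stem, " in ", path)
      cand[1]
    }
    mtx <- find1("matrix.mtx")
    bc  <- find1("barcodes.tsv")
    ft  <- tryCatch(find1("features.tsv"), error = function(e) find1("genes.tsv"))
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("malformed MatrixMarket file ", mtx,
                                           ": ", conditionMessage(e)))
    barcodes <- readLines(bc)
    feats <- utils::read.table(ft, sep = "\t", header = FALSE,
                               colClasses = "character", quote = "")
    if (nrow(m) != nrow(feats))
      stop("dimension mismatch: ", mtx, " has ", nrow(m), " rows but ", ft,
           " lists ", nrow(feats), " features")
    if (ncol(m) != length(barcodes))
      stop("dimension mismatch: ", mtx, " has ", ncol(m), " columns but ", bc,
           " lists ", length(barcodes), " barcodes")
    rownames(m) <- feats[[1]]
    colnames(m) <- barcodes
    gn <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
    return(expr_matrix(m, gene_names = gn, mito_prefix = mito_prefix))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE, quote = "")
  if (!nrow(tab) || !ncol(tab)) stop("empty count table: ", path)
  m <- as.matrix(tab)
  if (transpose) m <- t(m)
  expr_matrix(m, mito_prefix = mito_prefix)
}

#' Write an expression matrix as a 10x-style triplet directory
#'
#' @param x an `expr_matrix`
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "expr_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(rownames(x$counts), x$gene_names),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Quality-control filtering of cells
#'
#' Retains cells whose number of detected genes (raw count >= 1) lies in
#' `[min_genes, max_genes]` inclusive and whose mitochondrial UMI fraction
#' is at most `max_mito`. The bounds follow the usual droplet QC reading:
#' "fewer than 500 or more than 4000 genes" removes strictly outside
#' \[500, 4000\]; "more than 10% mitochondrial UMIs" removes strictly above
#' 0.10.
#'
#' @param x an `expr_matrix`
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_mito maximum mitochondrial UMI fraction (inclusive).
#' @return a list with `matrix` (the filtered `expr_matrix`) and `report`
#'   (data.frame: barcode, n_genes, mito_fraction, removed, reason).
#' @export
apply_qc <- function(x, min_genes = 500L, max_genes = 4000L, max_mito = 0.10) {
  stopifnot(inherits(x, "expr_matrix"),
            min_genes >= 1, min_genes <= max_genes,
            max_mito >= 0, max_mito <= 1)
  n_genes <- Matrix::colSums(x$counts >= 1)
  tot <- Matrix::colSums(x$counts)
  mito_frac <- ifelse(tot > 0,
                      Matrix::colSums(x$counts[x$mito, , drop = FALSE]) / tot, 0)
  low  <- n_genes < min_genes
  high <- n_genes > max_genes
  mito <- mito_frac > max_mito
  removed <- low | high | mito
  reason <- rep("", ncol(x$counts))
  reason[mito] <- "mito_fraction"
  reason[high] <- "too_many_genes"
  reason[low]  <- "too_few_genes"
  report <- data.frame(barcode = colnames(x$counts),
                       n_genes = as.integer(n_genes),
                       mito_fraction = as.numeric(mito_frac),
                       removed = removed, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (all(removed)) warning("all cells removed by QC")
  list(matrix = subset_cells(x, cells = !removed), report = report)
}

#' Median-scaling UMI normalization with natural-log transform
#'
#' Per-cell counts are divided by the cell's total UMI count, multiplied by
#' the median total across cells, and transformed as `log(1 + x)` so zeros
#' stay zero. The result is stored in the `normalized` layer.
#'
#' @param x an `expr_matrix` with positive per-cell totals.
#' @return the `expr_matrix` with `normalized` populated (sparse).
#' @export
normalize_umi <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  tot <- Matrix::colSums(x$counts)
  if (any(tot == 0))
    stop("cells with zero total counts present; run apply_qc() first")
  f <- stats::median(tot) / tot
  scaled <- x$counts %*% Matrix::Diagonal(x = f)
  norm <- scaled
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(x$counts)
  x$normalized <- methods::as(norm, "CsparseMatrix")
  x
}

#' Highly variable gene selection by binned normalized dispersion
#'
#' Per-gene mean and dispersion (variance / mean) are computed on the
#' de-logged normalized layer (`expm1`, i.e. the median-scaled linear
#' counts), dispersion is robustly z-scored (median/MAD) within equal-count
#' bins of mean expression, and the top `n_top` genes by this normalized
#' dispersion are returned, ties broken by gene id. Working on the linear
#' scale keeps the mean of an overdispersed gene comparable to its
#' same-abundance neighbours, so binning separates abundance from
#' variability; the robust centring keeps a bin's genuine high-variance
#' genes from masking each other.
#'
#' @param x a normalized `expr_matrix`
#' @param n_top number of genes to return.
#' @param n_bins number of equal-count mean-expression bins.
#' @return character vector of gene ids, ordered by decreasing normalized
#'   dispersion.
#' @export
select_hvg <- function(x, n_top = 2000L, n_bins = 20L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$normalized)) stop("normalized layer absent; run normalize_umi()")
  nm <- x$normalized
  nm@x <- expm1(nm@x)    # back to the median-scaled linear scale
  mu <- Matrix::rowMeans(nm)
  ex2 <- Matrix::rowMeans(nm^2)
  v <- (ex2 - mu^2) * ncol(nm) / max(1, ncol(nm) - 1)
  expressed <- mu > 0
  ids <- rownames(nm)[expressed]
  mu_e <- mu[expressed]; v_e <- v[expressed]
  if (!length(ids)) {
    warning("no expressed genes")
    return(character(0))
  }
  disp <- v_e / mu_e
  nb <- max(1L, min(n_bins, length(ids)))
  bins <- cut(rank(mu_e, ties.method = "first"),
              breaks = nb, labels = FALSE, include.lowest = TRUE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::mad(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else
      (disp[i] - stats::median(disp[i])) / s
  }
  if (length(ids) < n_top) {
    warning("fewer expressed genes (", length(ids), ") than n_top (", n_top, ")")
    n_top <- length(ids)
  }
  ids[order(-z, ids)][seq_len(n_top)]
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, tab-separated member gene ids.
#' Duplicate members within a set are dropped; member-less lines are skipped
#' with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors, with attribute `provenance`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(parts) < 3 || !length(members)) {
      warning("skipping empty gene set line: ", parts[1])
      next
    }
    sets[[parts[1]]] <- members
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene set names in ", path)
  attr(sets, "provenance") <- path
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell labeling table
#'
#' TSV with columns `barcode`, `population`, and optionally `sample`,
#' `condition`, `pseudotime`, `lineage`.
#'
#' @param path TSV file.
#' @return data.frame of labels.
#' @export
read_labels <- function(path) {
  lab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("barcode", "population") %in% names(lab)))
    stop("labels need at least columns barcode and population")
  if (anyDuplicated(lab$barcode)) stop("duplicate barcodes in labels")
  lab
}

#' @rdname read_labels
#' @param labels data.frame as returned by [read_labels()].
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# barcodes of one population, checking the labeling against the matrix
pop_cells <- function(x, labels, population) {
  bc <- labels$barcode[labels$population == population]
  if (!length(bc)) stop("population not found: ", population)
  missing <- setdiff(bc, colnames(x$counts))
  if (length(missing))
    stop("labeled barcodes absent from matrix, e.g. ", missing[1])
  bc
}
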