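#' Per-cell variant read-count matrix
#'
#' Holds, for every cell and variant site, the total and alternative-allele
#' read counts derived from the single-cell transcriptome.
#'
#' @param total cells x sites matrix of total read counts (rownames =
#'   barcodes, colnames = site ids such as `chr7:50382590_G>A`).
#' @param alt matching matrix of alternative-allele read counts
#'   (elementwise `alt <= total`).
#' @param sites optional data.frame (site, chrom, pos, ref, alt) describing
#'   the columns.
#' @return object of class `cell_variant_matrix`.
#' @export
cell_variant_matrix <- function(total, alt, sites = NULL) {
  total <- as.matrix(total); alt <- as.matrix(alt)
  if (!identical(dim(total), dim(alt))) stop("total/alt shape mismatch")
  if (is.null(rownames(total)) || is.null(colnames(total)))
    stop("total needs barcode rownames and site colnames")
  dimnames(alt) <- dimnames(total)
  if (any(total < 0) || any(alt < 0) || any(alt > total))
    stop("require 0 <= alt_reads <= total_reads")
  if (is.null(sites)) {
    sites <- parse_site_ids(colnames(total))
  }
  structure(list(total = total, alt = alt, sites = sites),
            class = "cell_variant_matrix")
}

parse_site_ids <- function(ids) {
  m <- regmatches(ids, regexec("^([^:]+):([0-9]+)_([A-Za-z]+)>([A-Za-z]+)$", ids))
  ok <- lengths(m) == 5
  data.frame(site = ids,
             chrom = ifelse(ok, vapply(m, function(v) if (length(v) == 5) v[2] else NA_character_, character(1)), NA),
             pos = ifelse(ok, as.integer(vapply(m, function(v) if (length(v) == 5) v[3] else NA_character_, character(1))), NA),
             ref = ifelse(ok, vapply(m, function(v) if (length(v) == 5) v[4] else NA_character_, character(1)), NA),
             alt = ifelse(ok, vapply(m, function(v) if (length(v) == 5) v[5] else NA_character_, character(1)), NA),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.cell_variant_matrix <- function(x, ...) {
  cat(sprintf("cell_variant_matrix: %d cells x %d sites\n",
              nrow(x$total), ncol(x$total)))
  invisible(x)
}

#' Read per-cell allele counts from a long-format TSV
#'
#' Columns: `barcode`, `chrom`, `pos`, `ref`, `alt`, `ref_reads`,
#' `alt_reads`. Missing (cell, site) combinations get zero reads.
#'
#' @param path TSV file.
#' @return a `cell_variant_matrix`.
#' @export
read_allele_counts <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("barcode", "chrom", "pos", "ref", "alt", "ref_reads", "alt_reads")
  if (!all(need %in% names(tab)))
    stop("allele count table needs columns: ", paste(need, collapse = ", "))
  site <- paste0(tab$chrom, ":", tab$pos, "_", tab$ref, ">", tab$alt)
  cells <- sort(unique(tab$barcode)); usite <- unique(site)
  tot <- matrix(0L, length(cells), length(usite),
                dimnames = list(cells, usite))
  alt <- tot
  i <- cbind(match(tab$barcode, cells), match(site, usite))
  tot[i] <- tab$ref_reads + tab$alt_reads
  alt[i] <- tab$alt_reads
  cell_variant_matrix(tot, alt)
}

#' @rdname read_allele_counts
#' @param cvm a `cell_variant_matrix`.
#' @export
write_allele_counts <- function(cvm, path) {
  stopifnot(inherits(cvm, "cell_variant_matrix"))
  keep <- which(cvm$total > 0, arr.ind = TRUE)
  site <- colnames(cvm$total)[keep[, 2]]
  info <- parse_site_ids(site)
  tab <- data.frame(barcode = rownames(cvm$total)[keep[, 1]],
                    chrom = info$chrom, pos = info$pos,
                    ref = info$ref, alt = info$alt,
                    ref_reads = cvm$total[keep] - cvm$alt[keep],
                    alt_reads = cvm$alt[keep],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$barcode, tab$chrom, tab$pos), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retention filtering of transcriptome-derived variant sites
#'
#' A site is kept when it satisfies all three rules: covered (total reads
#' of at least 1) in at least `min_called_cells` cells; deeply covered
#' (total reads exceeding `deep_read_floor`) in at least `min_deep_cells`
#' cells; and the
#' alternative allele observed (alt reads >= 1) in at least
#' `min_alt_cells` cells.
#'
#' @param cvm a `cell_variant_matrix`.
#' @param min_called_cells minimum covered cells (default 20).
#' @param min_deep_cells minimum deeply covered cells (default 5).
#' @param deep_read_floor read count a "deep" cell must exceed (default 2).
#' @param min_alt_cells minimum alt-carrying cells (default 3).
#' @return character vector of retained site ids.
#' @export
filter_variants <- function(cvm, min_called_cells = 20L, min_deep_cells = 5L,
                            deep_read_floor = 2L, min_alt_cells = 3L) {
  stopifnot(inherits(cvm, "cell_variant_matrix"))
  called <- colSums(cvm$total >= 1)
  deep <- colSums(cvm$total > deep_read_floor)
  carrier <- colSums(cvm$alt >= 1)
  colnames(cvm$total)[called >= min_called_cells &
                      deep >= min_deep_cells &
                      carrier >= min_alt_cells]
}

#' Per-cell variant call table
#'
#' A cell carries a variant when it shows at least `min_alt_reads`
#' alternative-allele reads at the site.
#'
#' @param cvm a `cell_variant_matrix`.
#' @param sites site ids to call (default all; typically
#'   [filter_variants()] output).
#' @param min_alt_reads carrier threshold (default 1).
#' @return data.frame: barcode, site, alt_reads, total_reads, carries.
#' @export
assign_cell_variants <- function(cvm, sites = NULL, min_alt_reads = 1L) {
  stopifnot(inherits(cvm, "cell_variant_matrix"))
  if (is.null(sites)) sites <- colnames(cvm$total)
  bad <- setdiff(sites, colnames(cvm$total))
  if (length(bad)) stop("unknown sites: ", paste(bad, collapse = ", "))
  tot <- cvm$total[, sites, drop = FALSE]
  alt <- cvm$alt[, sites, drop = FALSE]
  data.frame(barcode = rep(rownames(tot), times = length(sites)),
             site = rep(sites, each = nrow(tot)),
             alt_reads = as.integer(alt),
             total_reads = as.integer(tot),
             carries = as.vector(alt >= min_alt_reads),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Define a haplotype over ordered variant loci
#'
#' @param sites site ids (must be unique).
#' @param alleles for each site, which allele the haplotype carries
#'   (`"ref"` or `"alt"`).
#' @param name haplotype name.
#' @return object of class `haplotype`.
#' @export
haplotype <- function(sites, alleles, name = "alt_haplotype") {
  if (anyDuplicated(sites)) stop("duplicate haplotype loci")
  if (!length(sites)) stop("haplotype needs at least one locus")
  alleles <- match.arg(alleles, c("ref", "alt"), several.ok = TRUE)
  if (length(alleles) != length(sites)) stop("one allele per site required")
  structure(list(name = name, sites = sites, alleles = alleles),
            class = "haplotype")
}

#' @rdname haplotype
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `hap_allele`.
#' @export
read_haplotype <- function(path, name = "alt_haplotype") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "pos", "ref", "alt", "hap_allele")
  if (!all(need %in% names(tab)))
    stop("haplotype table needs columns: ", paste(need, collapse = ", "))
  haplotype(paste0(tab$chrom, ":", tab$pos, "_", tab$ref, ">", tab$alt),
            tab$hap_allele, name = name)
}

#' Haplotype assignment of single cells
#'
#' For each cell, loci of the haplotype with any read coverage are scored:
#' the observed allele (alt when alt reads >= 1, ref otherwise) is compared
#' with the haplotype allele, and the match count is tested against a
#' binomial null of chance agreement (`p0`, default 0.5) with the one-sided
#' tail `P(X >= n_matching | n_covered, p0)`. A cell is assigned the
#' haplotype only when both gates hold: more than `min_matching - 1`
#' matching loci and `p < alpha`.
#'
#' @param cvm a `cell_variant_matrix` covering the haplotype loci.
#' @param hap a `haplotype`.
#' @param min_matching minimum matching loci (default 6, i.e. "> 5").
#' @param alpha significance threshold (default 0.05).
#' @param p0 chance match probability under the null (default 0.5).
#' @return data.frame: barcode, n_covered, n_matching, p_value, assigned.
#' @export
haplotype_match <- function(cvm, hap, min_matching = 6L, alpha = 0.05,
                            p0 = 0.5) {
  stopifnot(inherits(cvm, "cell_variant_matrix"), inherits(hap, "haplotype"))
  missing <- setdiff(hap$sites, colnames(cvm$total))
  if (length(missing))
    stop("haplotype loci absent from matrix: ", paste(missing, collapse = ", "))
  tot <- cvm$total[, hap$sites, drop = FALSE]
  alt <- cvm$alt[, hap$sites, drop = FALSE]
  covered <- tot >= 1
  observed_alt <- alt >= 1
  hap_is_alt <- matrix(rep(hap$alleles == "alt", each = nrow(tot)),
                       nrow(tot), length(hap$sites))
  match_mat <- covered & (observed_alt == hap_is_alt)
  n_cov <- rowSums(covered)
  n_match <- rowSums(match_mat)
  p <- ifelse(n_cov == 0, 1,
              stats::pbinom(n_match - 1, n_cov, p0, lower.tail = FALSE))
  assigned <- n_match >= min_matching & p < alpha
  stopifnot(all(!assigned | (n_match >= min_matching & p < alpha)))
  data.frame(barcode = rownames(tot),
             n_covered = as.integer(n_cov),
             n_matching = as.integer(n_match),
             p_value = as.numeric(p),
             assigned = assigned,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variant burden per cell group
#'
#' Mean carried variants per cell and per-site carrier fractions for each
#' group (e.g. diagnosis vs relapse subpopulations).
#'
#' @param calls call table from [assign_cell_variants()].
#' @param groups named list (group -> barcodes) or a labeling data.frame
#'   (`barcode`, `population`).
#' @return list with `per_group` (data.frame: group, n_cells,
#'   mean_variants_per_cell) and `per_site` (data.frame: group, site,
#'   carrier_fraction).
#' @export
variant_burden <- function(calls, groups) {
  if (is.data.frame(groups))
    groups <- split(groups$barcode, groups$population)
  per_cell <- tapply(calls$carries, calls$barcode, sum)
  rows <- list(); site_rows <- list()
  for (g in names(groups)) {
    bc <- intersect(groups[[g]], names(per_cell))
    if (!length(bc)) {
      warning("group ", g, " has no called cells; excluded")
      next
    }
    rows[[g]] <- data.frame(group = g, n_cells = length(bc),
                            mean_variants_per_cell = mean(per_cell[bc]),
                            stringsAsFactors = FALSE)
    sub <- calls[calls$barcode %in% bc, ]
    cf <- tapply(sub$carries, sub$site, mean)
    site_rows[[g]] <- data.frame(group = g, site = names(cf),
                                 carrier_fraction = as.numeric(cf),
                                 stringsAsFactors = FALSE)
  }
  rbind0 <- function(l) {
    if (!length(l)) return(NULL)
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  list(per_group = rbind0(rows), per_site = rbind0(site_rows))
}

#' Read variant site definitions from a VCF
#'
#' Thin wrapper over `vcfR` returning a site table compatible with
#' [cell_variant_matrix()] column ids (1-based positions).
#'
#' @param path VCF file.
#' @return data.frame: site, chrom, pos, ref, alt.
#' @export
read_variant_sites <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF site definitions requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  data.frame(site = paste0(fix$CHROM, ":", fix$POS, "_", fix$REF, ">", fix$ALT),
             chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             stringsAsFactors = FALSE, row.names = NULL)
}
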