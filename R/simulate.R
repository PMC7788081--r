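#' Default reference population tree
#'
#' An 8-population hematopoiesis-like hierarchy used by the simulator: a
#' stem root (HSC) with multipotent, lympho-myeloid and
#' megakaryocyte-erythroid branches.
#'
#' @return a `pop_tree` over HSC, MPP, LMPP, CMP, CLP, GMP, MEP, ProB.
#' @export
default_tree <- function() {
  pop_tree(data.frame(
    parent = c("HSC", "MPP", "MPP", "LMPP", "CLP", "CMP", "CMP"),
    child  = c("MPP", "LMPP", "CMP", "CLP", "ProB", "GMP", "MEP")),
    root = "HSC")
}

#' Simulate a multi-lineage reference atlas
#'
#' Negative-binomial UMI counts for a tree of populations. The root
#' population expresses a baseline program (per-gene log-means drawn once);
#' each child inherits its parent's program and shifts a fresh random
#' marker-gene subset, so sibling populations are more similar than
#' distantly related ones — the premise that a query's nearest reference
#' program is its true counterpart.
#'
#' @param tree a `pop_tree` (default [default_tree()]).
#' @param n_genes number of genes (default 2000).
#' @param cells_per_pop cells per population (default 200).
#' @param n_markers marker genes shifted per population (default 100).
#' @param marker_lfc log-fold magnitude of marker shifts (natural log;
#'   default 1.5, random sign).
#' @param base_log_mean,base_log_sd distribution of per-gene baseline
#'   log-means (defaults give realistic per-cell totals around 1000-2000
#'   UMIs over 2000 genes).
#' @param dispersion negative-binomial size parameter (default 2; larger
#'   approaches Poisson).
#' @param seed integer seed (mandatory; the simulation is a pure function
#'   of its arguments).
#' @return list with `matrix` (an `expr_matrix`), `labels` (data.frame:
#'   barcode, population, sample, condition), `tree`, and `programs`
#'   (genes x populations matrix of log-means).
#' @export
simulate_atlas <- function(tree = default_tree(), n_genes = 2000L,
                           cells_per_pop = 200L, n_markers = 100L,
                           marker_lfc = 1.5, base_log_mean = log(0.5),
                           base_log_sd = 1.0, dispersion = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_genes < 1 || cells_per_pop < 1) stop("degenerate simulation spec")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  pops <- tree$nodes
  base <- stats::rnorm(n_genes, base_log_mean, base_log_sd)
  programs <- matrix(NA_real_, n_genes, length(pops),
                     dimnames = list(genes, pops))
  programs[, tree$root] <- base
  # breadth-first inheritance down the tree
  todo <- tree$root
  while (length(todo)) {
    parent <- todo[1]; todo <- todo[-1]
    kids <- tree$edges$child[tree$edges$parent == parent]
    for (k in kids) {
      prog <- programs[, parent]
      mk <- sample.int(n_genes, min(n_markers, n_genes))
      prog[mk] <- prog[mk] + sample(c(-1, 1), length(mk), TRUE) * marker_lfc
      programs[, k] <- prog
      todo <- c(todo, k)
    }
  }
  counts <- matrix(0L, n_genes, length(pops) * cells_per_pop)
  barcodes <- character(ncol(counts))
  pop_of <- character(ncol(counts))
  j <- 0
  for (p in pops) {
    mu <- exp(programs[, p])
    for (cc in seq_len(cells_per_pop)) {
      j <- j + 1
      counts[, j] <- stats::rnbinom(n_genes, size = dispersion, mu = mu)
      barcodes[j] <- sprintf("%s_c%03d", p, cc)
      pop_of[j] <- p
    }
  }
  dimnames(counts) <- list(genes, barcodes)
  labels <- data.frame(barcode = barcodes, population = pop_of,
                       sample = "reference", condition = "reference",
                       stringsAsFactors = FALSE)
  list(matrix = expr_matrix(counts), labels = labels, tree = tree,
       programs = programs)
}

#' Simulate query populations with known counterparts
#'
#' Each query population draws counts from its true counterpart's
#' expression program after perturbing a random subset of genes — a
#' leukemia-like shift away from the healthy program whose size is
#' controlled by `perturb_frac` and `perturb_lfc`.
#'
#' @param atlas result of [simulate_atlas()].
#' @param counterparts named character vector: query population name ->
#'   true counterpart (a population of the atlas).
#' @param cells_per_pop cells per query population (default 200).
#' @param perturb_frac fraction of genes shifted (default 0.10).
#' @param perturb_lfc log-fold magnitude of the shift (default 1.0, random
#'   sign).
#' @param dispersion negative-binomial size (default as in the atlas: 2).
#' @param seed integer seed.
#' @return list with `matrix` (an `expr_matrix`), `labels`, and `truth`
#'   (data.frame: query, true_counterpart).
#' @export
simulate_queries <- function(atlas, counterparts, cells_per_pop = 200L,
                             perturb_frac = 0.10, perturb_lfc = 1.0,
                             dispersion = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (perturb_frac < 0 || perturb_frac > 1)
    stop("perturb_frac must be in [0, 1]")
  bad <- setdiff(counterparts, colnames(atlas$programs))
  if (length(bad)) stop("unknown counterparts: ", paste(bad, collapse = ", "))
  if (is.null(names(counterparts)))
    names(counterparts) <- paste0("Q", seq_along(counterparts))
  set.seed(seed)
  n_genes <- nrow(atlas$programs)
  genes <- rownames(atlas$programs)
  counts <- matrix(0L, n_genes, length(counterparts) * cells_per_pop)
  barcodes <- character(ncol(counts)); pop_of <- character(ncol(counts))
  j <- 0
  for (q in names(counterparts)) {
    prog <- atlas$programs[, counterparts[[q]]]
    n_shift <- round(perturb_frac * n_genes)
    if (n_shift > 0) {
      sh <- sample.int(n_genes, n_shift)
      prog[sh] <- prog[sh] + sample(c(-1, 1), n_shift, TRUE) * perturb_lfc
    }
    mu <- exp(prog)
    for (cc in seq_len(cells_per_pop)) {
      j <- j + 1
      counts[, j] <- stats::rnbinom(n_genes, size = dispersion, mu = mu)
      barcodes[j] <- sprintf("%s_c%03d", q, cc)
      pop_of[j] <- q
    }
  }
  dimnames(counts) <- list(genes, barcodes)
  labels <- data.frame(barcode = barcodes, population = pop_of,
                       sample = "query", condition = "query",
                       stringsAsFactors = FALSE)
  truth <- data.frame(query = names(counterparts),
                      true_counterpart = unname(counterparts),
                      stringsAsFactors = FALSE)
  list(matrix = expr_matrix(counts), labels = labels, truth = truth)
}

#' Simulate a hallmark-like gene-set collection
#'
#' Random gene sets over a gene universe, mimicking the size range of the
#' 50 MSigDB hallmark collections.
#'
#' @param genes gene universe.
#' @param n_sets number of sets (default 50).
#' @param size_range inclusive range of set sizes (default 30-80).
#' @param seed integer seed.
#' @return named list of gene-id vectors.
#' @export
simulate_gene_sets <- function(genes, n_sets = 50L, size_range = c(30L, 80L),
                               seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, sample(size_range[1]:size_range[2], 1)))
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  sets
}

#' Simulate a two-clone variant/haplotype fixture
#'
#' Cells belong to one of two clones; sites are covered at random depths
#' and the alternative allele appears with clone-specific probabilities
#' (planted clone-specific variants). One clone additionally carries an
#' alternative haplotype over a separate block of loci.
#'
#' @param n_cells_per_clone cells per clone (default 100).
#' @param n_sites variant sites (default 20).
#' @param n_hap_loci haplotype loci (default 39).
#' @param alt_prob_carrier,alt_prob_other probability that a covered site
#'   shows the alt allele in the carrier clone / the other clone.
#' @param coverage_prob per-locus probability that a cell has any reads
#'   (default 0.5).
#' @param mean_depth mean read depth where covered (Poisson, shifted by 1).
#' @param hap_error_rate probability a covered haplotype locus shows the
#'   wrong allele (sequencing/allelic dropout noise; default 0.1).
#' @param seed integer seed.
#' @return list with `cvm` (a `cell_variant_matrix` over the variant
#'   sites), `hap_cvm` (matrix over the haplotype loci), `hap` (the
#'   `haplotype`), and `clones` (data.frame: barcode, clone,
#'   carries_haplotype).
#' @export
simulate_variant_fixture <- function(n_cells_per_clone = 100L, n_sites = 20L,
                                     n_hap_loci = 39L,
                                     alt_prob_carrier = 0.8,
                                     alt_prob_other = 0.05,
                                     coverage_prob = 0.5, mean_depth = 2,
                                     hap_error_rate = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(alt_prob_carrier >= 0, alt_prob_carrier <= 1,
            alt_prob_other >= 0, alt_prob_other <= 1,
            coverage_prob >= 0, coverage_prob <= 1)
  set.seed(seed)
  n <- 2L * n_cells_per_clone
  barcodes <- sprintf("cell%03d", seq_len(n))
  clone <- rep(c("clone1", "clone2"), each = n_cells_per_clone)
  carrier <- clone == "clone2"
  draw_block <- function(n_loci, alt_prob_by_cell) {
    sites <- sprintf("chr%d:%d_G>A", sample(1:22, n_loci, TRUE),
                     sample.int(2e8, n_loci))
    covered <- matrix(stats::rbinom(n * n_loci, 1, coverage_prob), n, n_loci)
    depth <- covered * (1L + stats::rpois(n * n_loci, mean_depth - 1))
    is_alt <- matrix(stats::rbinom(n * n_loci, 1,
                                   rep(alt_prob_by_cell, n_loci)), n, n_loci)
    alt <- depth * is_alt
    dimnames(depth) <- dimnames(alt) <- list(barcodes, sites)
    list(total = depth, alt = alt)
  }
  vb <- draw_block(n_sites, ifelse(carrier, alt_prob_carrier, alt_prob_other))
  # haplotype block: carrier cells show the alt haplotype allele, others the
  # reference allele, each flipped with hap_error_rate
  hap_sites <- sprintf("chr5:%d_A>G", 80700000L + seq_len(n_hap_loci) * 997L)
  covered <- matrix(stats::rbinom(n * n_hap_loci, 1, coverage_prob),
                    n, n_hap_loci)
  depth <- covered * (1L + stats::rpois(n * n_hap_loci, mean_depth - 1))
  err <- matrix(stats::rbinom(n * n_hap_loci, 1, hap_error_rate),
                n, n_hap_loci)
  shows_alt <- (matrix(carrier, n, n_hap_loci) + err) %% 2 == 1
  hap_alt <- depth * shows_alt
  dimnames(depth) <- dimnames(hap_alt) <- list(barcodes, hap_sites)
  list(cvm = cell_variant_matrix(vb$total, vb$alt),
       hap_cvm = cell_variant_matrix(depth, hap_alt),
       hap = haplotype(hap_sites, rep("alt", n_hap_loci), name = "alt_haplo"),
       clones = data.frame(barcode = barcodes, clone = clone,
                           carries_haplotype = carrier,
                           stringsAsFactors = FALSE))
}
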