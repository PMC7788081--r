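#' Posterior table of a fit in long form
#'
#' One row per (query population, reference population, channel) with the
#' channel likelihood and posterior, the combined posterior, and the
#' assignment.
#'
#' @param fit a `cci` fit.
#' @return data.frame: query_pop, reference_pop, channel, likelihood,
#'   posterior, combined, assigned, margin.
#' @export
posterior_table <- function(fit) {
  stopifnot(inherits(fit, "cci"))
  rows <- list()
  for (qp in fit$query_pops) {
    post <- fit$posteriors[[qp]]
    asg <- fit$assignments[fit$assignments$query == qp, ]
    for (ch in fit$channels) for (rp in fit$ref_pops) {
      rows[[length(rows) + 1]] <- data.frame(
        query_pop = qp, reference_pop = rp, channel = ch,
        likelihood = unname(fit$likelihoods[[qp]][[ch]][rp]),
        posterior = unname(post$posterior[ch, rp]),
        combined = unname(post$combined[rp]),
        assigned = rp == asg$counterpart,
        margin = asg$margin, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

usage_error <- function(msg) {
  stop(structure(class = c("ccimap_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) usage_error(paste("unexpected argument:", a))
    if (i == length(argv) || startsWith(argv[i + 1], "--"))
      usage_error(paste("flag", a, "needs a value"))
    flags[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  flags
}

run_config <- function(flags) {
  cfg <- list()
  if (!is.null(flags$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("--config requires the yaml package")
    cfg <- yaml::read_yaml(flags$config)
    flags$config <- NULL
  }
  cfg[names(flags)] <- flags  # flags win over the config file
  cfg
}

cfg_num <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
}

cfg_chr <- function(cfg, key, default = NULL, required = FALSE) {
  v <- cfg[[key]]
  if (is.null(v)) {
    if (required) usage_error(paste("missing required option --", key, sep = ""))
    return(default)
  }
  as.character(v)
}

cfg_seed <- function(cfg) {
  if (is.null(cfg$seed)) usage_error("--seed is mandatory for this command")
  as.integer(cfg$seed)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(out_dir, subcommand, cfg, inputs, artifacts) {
  inputs <- unlist(lapply(inputs[file.exists(inputs)], function(p)
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p))
  inputs <- unique(as.character(inputs[!is.na(inputs)]))
  md5 <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "ccimap",
    version = as.character(utils::packageVersion("ccimap")),
    subcommand = subcommand,
    config = cfg,
    input_md5 = md5,
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a pipeline subcommand
#'
#' The programmatic command-line surface: dispatches one of the pipeline
#' subcommands on a flag list (`--key value` pairs, optionally preceded by
#' `--config file.yaml`; flags win over the config file), writes its TSV
#' artifacts and a JSON run manifest (package version, seed, config echo,
#' input checksums) into `--out`, and returns the artifact paths. Every
#' stochastic subcommand requires `--seed`. Inputs are never mutated. The
#' shell entry point `ccimap.R` under the package's `cli/` directory is a
#' thin wrapper around this function.
#'
#' @param argv character vector: subcommand followed by flags, e.g.
#'   `c("simulate", "--seed", "1", "--out", "sim")`.
#' @return named character vector of artifact paths, invisibly.
#' @export
cci_run <- function(argv) {
  if (!length(argv)) usage_error("no subcommand given")
  sub <- argv[1]
  known <- c("simulate", "qc", "normalize", "cci", "gsea", "grn", "entropy",
             "variants", "haplotype")
  if (!sub %in% known)
    usage_error(paste0("unknown subcommand '", sub, "'; expected one of: ",
                       paste(known, collapse = ", ")))
  cfg <- run_config(parse_flags(argv[-1]))
  out_dir <- cfg_chr(cfg, "out", required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  art <- switch(sub,
    simulate = run_simulate(cfg, out_dir),
    qc = , normalize = run_qc_norm(sub, cfg, out_dir),
    cci = run_cci(cfg, out_dir),
    gsea = run_gsea(cfg, out_dir),
    grn = run_grn(cfg, out_dir),
    entropy = run_entropy(cfg, out_dir),
    variants = run_variants(cfg, out_dir),
    haplotype = run_haplotype(cfg, out_dir))
  for (key in c("counts", "ref", "query", "ref_labels", "query_labels",
                "labels", "sets", "tree", "alleles", "haplotype", "targets",
                "priors"))
    if (!is.null(cfg[[key]])) inputs <- c(inputs, cfg[[key]])
  write_manifest(out_dir, sub, cfg, inputs, as.list(art))
  invisible(art)
}

run_simulate <- function(cfg, out_dir) {
  seed <- cfg_seed(cfg)
  atlas <- simulate_atlas(n_genes = cfg_num(cfg, "n_genes", 2000),
                          cells_per_pop = cfg_num(cfg, "cells_per_pop", 200),
                          seed = seed)
  n_query <- cfg_num(cfg, "n_query", 4)
  set.seed(seed)
  cps <- sample(setdiff(atlas$tree$nodes, atlas$tree$root), n_query)
  queries <- simulate_queries(atlas, stats::setNames(cps, paste0("Q", seq_len(n_query))),
                              cells_per_pop = cfg_num(cfg, "cells_per_pop", 200),
                              perturb_frac = cfg_num(cfg, "perturb_frac", 0.10),
                              perturb_lfc = cfg_num(cfg, "perturb_lfc", 1.0),
                              seed = seed + 1L)
  sets <- simulate_gene_sets(rownames(atlas$matrix$counts), seed = seed + 2L)
  p <- function(...) file.path(out_dir, ...)
  write_counts(atlas$matrix, p("reference"))
  write_counts(queries$matrix, p("query"))
  art <- c(reference = p("reference"), query = p("query"),
           ref_labels = write_tsv(atlas$labels, p("ref_labels.tsv")),
           query_labels = write_tsv(queries$labels, p("query_labels.tsv")),
           truth = write_tsv(queries$truth, p("truth.tsv")),
           tree = write_tsv(atlas$tree$edges, p("tree.tsv")),
           gene_sets = write_gmt(sets, p("gene_sets.gmt")))
  fix <- simulate_variant_fixture(seed = seed + 3L)
  art <- c(art,
           alleles = write_allele_counts(fix$cvm, p("alleles.tsv")),
           hap_alleles = write_allele_counts(fix$hap_cvm, p("hap_alleles.tsv")),
           haplotype = {
             info <- parse_site_ids(fix$hap$sites)
             write_tsv(data.frame(chrom = info$chrom, pos = info$pos,
                                  ref = info$ref, alt = info$alt,
                                  hap_allele = fix$hap$alleles),
                       p("haplotype.tsv"))
           },
           clones = write_tsv(fix$clones, p("clones.tsv")))
  art
}

run_qc_norm <- function(sub, cfg, out_dir) {
  em <- read_counts(cfg_chr(cfg, "counts", required = TRUE),
                    mito_prefix = cfg_chr(cfg, "mito_prefix", "MT-"))
  qc <- apply_qc(em,
                 min_genes = cfg_num(cfg, "min_genes", 500),
                 max_genes = cfg_num(cfg, "max_genes", 4000),
                 max_mito = cfg_num(cfg, "max_mito", 0.10))
  art <- c(qc_report = write_tsv(qc$report, file.path(out_dir, "qc_report.tsv")))
  if (sub == "qc") {
    write_counts(qc$matrix, file.path(out_dir, "filtered"))
    return(c(art, filtered = file.path(out_dir, "filtered")))
  }
  nm <- normalize_umi(qc$matrix)
  Matrix::writeMM(nm$normalized, file.path(out_dir, "normalized.mtx"))
  writeLines(colnames(nm$normalized), file.path(out_dir, "barcodes.tsv"))
  writeLines(rownames(nm$normalized), file.path(out_dir, "genes.tsv"))
  c(art, normalized = file.path(out_dir, "normalized.mtx"))
}

load_normalized <- function(path, mito_prefix = "MT-") {
  normalize_umi(read_counts(path, mito_prefix = mito_prefix))
}

run_cci <- function(cfg, out_dir) {
  seed <- cfg_seed(cfg)
  ref <- load_normalized(cfg_chr(cfg, "ref", required = TRUE))
  query <- load_normalized(cfg_chr(cfg, "query", required = TRUE))
  ref_labels <- read_labels(cfg_chr(cfg, "ref_labels", required = TRUE))
  query_labels <- read_labels(cfg_chr(cfg, "query_labels", required = TRUE))
  sets_path <- cfg_chr(cfg, "sets")
  sets <- if (!is.null(sets_path)) read_gmt(sets_path) else NULL
  tree_path <- cfg_chr(cfg, "tree")
  tree <- if (!is.null(tree_path))
    read_tree(tree_path, root = cfg_chr(cfg, "root", required = TRUE)) else NULL
  channels <- c("euclidean", "spearman", "pc_dist",
                if (!is.null(sets)) "gsea_profile")
  priors <- NULL
  if (!is.null(cfg$priors)) {
    pt <- utils::read.table(cfg$priors, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    priors <- stats::setNames(pt[[2]], pt[[1]])
  }
  fit <- cci(ref, ref_labels, query, query_labels, gene_sets = sets,
             tree = tree, channels = channels,
             n_resamples = cfg_num(cfg, "n_resamples", 10000),
             size = cfg_num(cfg, "size", 30),
             n_hvg = cfg_num(cfg, "n_hvg", 2000),
             n_pc = cfg_num(cfg, "n_pc", 30),
             L = cfg_num(cfg, "L", 5000),
             priors = priors, eps = cfg_num(cfg, "eps", 1e-6),
             seed = seed)
  art <- c(posteriors = write_tsv(posterior_table(fit),
                                  file.path(out_dir, "posteriors.tsv")),
           assignments = write_tsv(fit$assignments,
                                   file.path(out_dir, "assignments.tsv")))
  if (!is.null(tree)) {
    rep <- mapping_report(fit, query_labels = query_labels)
    jsonlite::write_json(rep, file.path(out_dir, "mapping_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    art <- c(art,
             mapping_report = file.path(out_dir, "mapping_report.json"),
             mapping_per_sample = write_tsv(rep$per_sample,
                                            file.path(out_dir, "mapping_per_sample.tsv")))
  }
  art
}

run_gsea <- function(cfg, out_dir) {
  seed <- cfg_seed(cfg)
  em <- load_normalized(cfg_chr(cfg, "counts", required = TRUE))
  labels <- read_labels(cfg_chr(cfg, "labels", required = TRUE))
  sets <- read_gmt(cfg_chr(cfg, "sets", required = TRUE))
  pa <- cfg_chr(cfg, "pop_a", required = TRUE)
  pb <- cfg_chr(cfg, "pop_b", required = TRUE)
  n <- cfg_num(cfg, "n", 10000)
  set.seed(seed)
  rows <- lapply(names(sets), function(s) {
    z <- enrichment_z(em, labels, pa, pb, sets[[s]], n = n,
                      size = cfg_num(cfg, "size", 30),
                      L = cfg_num(cfg, "L", 5000))
    data.frame(pop_a = pa, pop_b = pb, gene_set = s, z = z$z,
               mean_auc_a = z$mean_a, mean_auc_b = z$mean_b, n = n,
               stringsAsFactors = FALSE)
  })
  c(z_scores = write_tsv(do.call(rbind, rows),
                         file.path(out_dir, "gsea_z.tsv")))
}

run_grn <- function(cfg, out_dir) {
  seed <- cfg_seed(cfg)
  em <- load_normalized(cfg_chr(cfg, "counts", required = TRUE))
  labels <- read_labels(cfg_chr(cfg, "labels", required = TRUE))
  if (!"pseudotime" %in% names(labels))
    usage_error("labels must carry a pseudotime column for grn")
  targets <- read_gmt(cfg_chr(cfg, "targets", required = TRUE))
  keep <- labels$barcode[is.finite(labels$pseudotime)]
  em <- subset_cells(em, cells = keep)
  t <- labels$pseudotime[match(keep, labels$barcode)]
  set.seed(seed)
  rows <- lapply(names(targets), function(reg) {
    g <- grn_score(em, reg, targets[[reg]], t,
                   bins = cfg_num(cfg, "bins", 10),
                   n_perm = cfg_num(cfg, "n_perm", 100))
    data.frame(regulator = reg, c = g$c, m = g$m, n = g$n, score = g$score,
               stringsAsFactors = FALSE)
  })
  grn <- do.call(rbind, rows)
  grn <- grn[order(-grn$score), ]
  art <- c(grn_scores = write_tsv(grn, file.path(out_dir, "grn_scores.tsv")))
  coord <- lineage_tfs(em, names(targets), t,
                       fdr = cfg_num(cfg, "fdr", 0.05))
  art <- c(art, lineage_tfs = write_tsv(coord,
                                        file.path(out_dir, "lineage_tfs.tsv")))
  net <- build_tf_network(em, coord$tf[coord$coordinated],
                          r_threshold = cfg_num(cfg, "r_threshold", 0.1),
                          min_degree = cfg_num(cfg, "min_degree", 5))
  c(art,
    network_nodes = write_tsv(net$nodes, file.path(out_dir, "network_nodes.tsv")),
    network_edges = write_tsv(net$edges, file.path(out_dir, "network_edges.tsv")))
}

run_entropy <- function(cfg, out_dir) {
  em <- read_counts(cfg_chr(cfg, "counts", required = TRUE))
  art <- c(entropy = write_tsv(cell_entropies(em),
                               file.path(out_dir, "entropy.tsv")))
  if (!is.null(cfg$labels)) {
    labels <- read_labels(cfg$labels)
    art <- c(art, entropy_summary = write_tsv(
      entropy_summary(em, labels), file.path(out_dir, "entropy_summary.tsv")))
  }
  art
}

run_variants <- function(cfg, out_dir) {
  cvm <- read_allele_counts(cfg_chr(cfg, "alleles", required = TRUE))
  retained <- filter_variants(cvm,
    min_called_cells = cfg_num(cfg, "min_called_cells", 20),
    min_deep_cells = cfg_num(cfg, "min_deep_cells", 5),
    deep_read_floor = cfg_num(cfg, "deep_read_floor", 2),
    min_alt_cells = cfg_num(cfg, "min_alt_cells", 3))
  calls <- assign_cell_variants(cvm, retained,
    min_alt_reads = cfg_num(cfg, "min_alt_reads", 1))
  art <- c(retained = write_tsv(data.frame(site = retained),
                                file.path(out_dir, "retained_sites.tsv")),
           calls = write_tsv(calls, file.path(out_dir, "variant_calls.tsv")))
  if (!is.null(cfg$labels)) {
    labels <- read_labels(cfg$labels)
    burden <- variant_burden(calls, labels)
    art <- c(art, burden = write_tsv(burden$per_group,
                                     file.path(out_dir, "variant_burden.tsv")))
  }
  art
}

run_haplotype <- function(cfg, out_dir) {
  cvm <- read_allele_counts(cfg_chr(cfg, "alleles", required = TRUE))
  hap <- read_haplotype(cfg_chr(cfg, "haplotype", required = TRUE))
  calls <- haplotype_match(cvm, hap,
    min_matching = cfg_num(cfg, "min_matching", 6),
    alpha = cfg_num(cfg, "alpha", 0.05),
    p0 = cfg_num(cfg, "p0", 0.5))
  c(haplotype_calls = write_tsv(calls,
                                file.path(out_dir, "haplotype_calls.tsv")))
}
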