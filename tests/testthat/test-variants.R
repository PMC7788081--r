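# cvm with controlled per-site coverage and carrier counts
boundary_cvm <- function(n_cells = 40) {
  cells <- sprintf("cell%02d", 1:n_cells)
  mk_site <- function(n_called, n_deep, n_alt) {
    tot <- integer(n_cells); alt <- integer(n_cells)
    tot[seq_len(n_called)] <- 1L
    tot[seq_len(min(n_deep, n_called))] <- 3L     # "deep" means > 2 reads
    alt[seq_len(min(n_alt, n_called))] <- 1L
    list(tot = tot, alt = alt)
  }
  spec <- list(s_called19 = c(19, 6, 4),  # fails rule 1 (19 < 20 covered)
               s_called20 = c(20, 6, 4),  # passes all
               s_deep4    = c(25, 4, 4),  # fails rule 2
               s_deep5    = c(25, 5, 4),  # passes all
               s_alt2     = c(25, 6, 2),  # fails rule 3
               s_alt3     = c(25, 6, 3))  # passes all
  tot <- sapply(spec, function(v) mk_site(v[1], v[2], v[3])$tot)
  alt <- sapply(spec, function(v) mk_site(v[1], v[2], v[3])$alt)
  rownames(tot) <- rownames(alt) <- cells
  cell_variant_matrix(tot, alt, sites = data.frame(site = colnames(tot)))
}

test_that("variant retention applies the three rules at their printed boundaries", {
  cvm <- boundary_cvm()
  kept <- filter_variants(cvm)
  expect_setequal(kept, c("s_called20", "s_deep5", "s_alt3"))
})

test_that("variant retention equals a brute-force three-rule oracle on a seeded fixture", {
  set.seed(61)
  n_cells <- 50; n_sites <- 20
  tot <- matrix(rpois(n_cells * n_sites, 0.9), n_cells, n_sites,
                dimnames = list(sprintf("c%02d", 1:n_cells),
                                sprintf("chr1:%d_A>G", 1000 + 1:n_sites)))
  alt <- matrix(0L, n_cells, n_sites, dimnames = dimnames(tot))
  alt[tot > 0] <- rbinom(sum(tot > 0), tot[tot > 0], 0.3)
  cvm <- cell_variant_matrix(tot, alt)
  kept <- filter_variants(cvm, min_called_cells = 10)
  oracle <- colnames(tot)[vapply(seq_len(n_sites), function(j) {
    sum(tot[, j] >= 1) >= 10 && sum(tot[, j] > 2) >= 5 && sum(alt[, j] >= 1) >= 3
  }, logical(1))]
  expect_identical(kept, oracle)
})

test_that("relaxing any retention threshold never drops a retained site", {
  set.seed(62)
  tot <- matrix(rpois(50 * 15, 1.2), 50, 15,
                dimnames = list(sprintf("c%02d", 1:50), sprintf("s%02d", 1:15)))
  alt <- matrix(rbinom(50 * 15, tot, 0.4), 50, 15, dimnames = dimnames(tot))
  cvm <- cell_variant_matrix(tot, alt)
  base <- filter_variants(cvm, min_called_cells = 15, min_deep_cells = 4,
                          deep_read_floor = 2, min_alt_cells = 3)
  relaxed <- list(
    filter_variants(cvm, min_called_cells = 10, min_deep_cells = 4,
                    deep_read_floor = 2, min_alt_cells = 3),
    filter_variants(cvm, min_called_cells = 15, min_deep_cells = 2,
                    deep_read_floor = 2, min_alt_cells = 3),
    filter_variants(cvm, min_called_cells = 15, min_deep_cells = 4,
                    deep_read_floor = 1, min_alt_cells = 3),
    filter_variants(cvm, min_called_cells = 15, min_deep_cells = 4,
                    deep_read_floor = 2, min_alt_cells = 1))
  for (r in relaxed) expect_true(all(base %in% r))
})

test_that("per-cell variant calls follow the alt-read threshold exactly", {
  cvm <- boundary_cvm()
  calls <- assign_cell_variants(cvm)
  expect_identical(calls$carries, calls$alt_reads >= 1)
  strict <- assign_cell_variants(cvm, min_alt_reads = 2)
  expect_identical(strict$carries, strict$alt_reads >= 2)
  expect_error(assign_cell_variants(cvm, sites = "nope"), "unknown sites")
})

test_that("haplotype assignment needs both the >5-loci gate and the binomial p", {
  sites <- sprintf("chr5:%d_A>G", 100 + 1:10)
  hap <- haplotype(sites, rep("alt", 10))
  tot <- matrix(0L, 3, 10, dimnames = list(c("six_of_six", "six_of_ten",
                                             "five_of_five"), sites))
  alt <- tot
  tot["six_of_six", 1:6] <- 1L; alt["six_of_six", 1:6] <- 1L
  tot["six_of_ten", ] <- 1L;    alt["six_of_ten", 1:6] <- 1L
  tot["five_of_five", 1:5] <- 1L; alt["five_of_five", 1:5] <- 1L
  calls <- haplotype_match(cell_variant_matrix(tot, alt), hap)
  calls <- calls[match(rownames(tot), calls$barcode), ]
  expect_equal(calls$p_value, c(1 / 64, 386 / 1024, 1 / 32), tolerance = 1e-12)
  expect_identical(calls$assigned, c(TRUE, FALSE, FALSE))
})

test_that("haplotype p-values equal the exact binomial tail", {
  set.seed(63)
  sites <- sprintf("chr5:%d_A>G", 200 + 1:39)
  hap <- haplotype(sites, rep("alt", 39))
  cases <- do.call(rbind, lapply(1:39, function(n)
    cbind(n, unique(c(0, n, sample(0:n, min(3, n + 1)))))))
  tot <- matrix(0L, nrow(cases), 39)
  alt <- matrix(0L, nrow(cases), 39)
  rownames(tot) <- rownames(alt) <- sprintf("cell%03d", seq_len(nrow(cases)))
  colnames(tot) <- colnames(alt) <- sites
  for (i in seq_len(nrow(cases))) {
    n <- cases[i, 1]; k <- cases[i, 2]
    tot[i, seq_len(n)] <- 1L
    alt[i, seq_len(k)] <- 1L            # k matching (alt), n - k mismatching
  }
  calls <- haplotype_match(cell_variant_matrix(tot, alt), hap)
  for (i in seq_len(nrow(cases))) {
    n <- cases[i, 1]; k <- cases[i, 2]
    expect_equal(calls$p_value[i], oracle_binom_tail(k, n), tolerance = 1e-12)
  }
  expect_true(all(calls$assigned == (calls$n_matching >= 6 & calls$p_value < 0.05)))
})

test_that("variant burden separates planted clones and respects symmetry", {
  # two identical groups -> identical rows
  cvm <- boundary_cvm()
  calls <- assign_cell_variants(cvm)
  groups <- list(g1 = rownames(cvm$total)[1:20], g2 = rownames(cvm$total)[1:20])
  vb <- variant_burden(calls, groups)
  expect_equal(vb$per_group$mean_variants_per_cell[1],
               vb$per_group$mean_variants_per_cell[2])
  # a group with no carried variants has mean 0
  none <- variant_burden(calls, list(clean = rownames(cvm$total)[31:40]))
  expect_equal(none$per_group$mean_variants_per_cell, 0)

  # planted clone-specific variants: carrier clone mean higher in 10/10 seeds
  wins <- vapply(1:10, function(s) {
    fix <- simulate_variant_fixture(n_cells_per_clone = 60, seed = s)
    calls <- assign_cell_variants(fix$cvm)
    vb <- variant_burden(calls, split(fix$clones$barcode, fix$clones$clone))
    g <- vb$per_group
    g$mean_variants_per_cell[g$group == "clone2"] >
      g$mean_variants_per_cell[g$group == "clone1"]
  }, logical(1))
  expect_true(all(wins))
})

test_that("VCF site definitions parse into the site-id convention", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr7\t50382590\t.\tG\tA\t.\tPASS\t.",
    "chr13\t48409776\t.\tT\tC\t.\tPASS\t."), f)
  sites <- read_variant_sites(f)
  expect_identical(sites$site,
                   c("chr7:50382590_G>A", "chr13:48409776_T>C"))
  expect_identical(sites$pos, c(50382590L, 48409776L))
})

test_that("allele-count tables round-trip through the long TSV format", {
  fix <- simulate_variant_fixture(n_cells_per_clone = 20, n_sites = 8,
                                  seed = 64)
  f <- tempfile(fileext = ".tsv")
  write_allele_counts(fix$cvm, f)
  back <- read_allele_counts(f)
  covered <- colnames(fix$cvm$total)[colSums(fix$cvm$total) > 0]
  cells <- rownames(back$total)
  expect_true(all(back$total[cells, sort(covered)] ==
                  fix$cvm$total[cells, sort(covered)]))
  expect_true(all(back$alt[cells, sort(covered)] ==
                  fix$cvm$alt[cells, sort(covered)]))
})
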