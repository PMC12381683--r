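test_that("draw_pop_freqs collapses to the ancestral frequency at F = 0 and rejects degenerate input", {
  expect_equal(draw_pop_freqs(0.5, 0), list(p_hl = 0.5, p_ll = 0.5))
  expect_equal(draw_pop_freqs(c(0.2, 0.8), 0),
               list(p_hl = c(0.2, 0.8), p_ll = c(0.2, 0.8)))
  expect_error(draw_pop_freqs(0, 0.1), "inside")
  expect_error(draw_pop_freqs(1, 0.1), "inside")
  expect_error(draw_pop_freqs(0.5, 1), "target_fst")
})

test_that("draw_pop_freqs at extreme differentiation concentrates mass near fixation", {
  f <- draw_pop_freqs(rep(0.9, 2000), 0.99, seed = 11)
  extreme <- mean(f$p_hl < 0.05 | f$p_hl > 0.95)
  expect_gt(extreme, 0.9)
  expect_true(all(f$p_hl >= 0 & f$p_hl <= 1))
  ## variance approaches the Balding-Nichols maximum p(1-p)F
  expect_gt(var(f$p_hl), 0.9 * 0.9 * 0.1 * 0.99 * 0.8)
})

test_that("simulated cohorts are byte-identical under the same seed", {
  cfg <- sim_config(n_variants = 100, chrom_lengths = c(chr1 = 5e6),
                    len_range = c(1e3, 5e3), seed = 7)
  s1 <- simulate_genotype_matrix(cfg)
  s2 <- simulate_genotype_matrix(cfg)
  expect_identical(s1, s2)
  v1 <- tempfile(fileext = ".vcf"); v2 <- tempfile(fileext = ".vcf")
  write_sv_vcf(s1$sv, v1); write_sv_vcf(s2$sv, v2)
  expect_identical(readLines(v1), readLines(v2))
  s3 <- simulate_genotype_matrix(sim_config(n_variants = 100,
                                            chrom_lengths = c(chr1 = 5e6),
                                            len_range = c(1e3, 5e3), seed = 8))
  expect_false(identical(s1$sv$geno, s3$sv$geno))
})

test_that("realized missingness matches the configured rate", {
  cfg <- sim_config(n_variants = 400, n_hl = 15, n_ll = 15,
                    chrom_lengths = c(chr1 = 2e7), len_range = c(1e3, 5e3),
                    missing_rate = 0.5, seed = 21)
  sim <- simulate_genotype_matrix(cfg)
  expect_equal(mean(is.na(sim$sv$geno)), 0.5, tolerance = 0.02 / 0.5)
})

test_that("variant intervals never overlap within a chromosome and lengths respect the range", {
  cfg <- sim_config(n_variants = 300, chrom_lengths = c(chrA = 1e7, chrB = 5e6),
                    len_range = c(1e3, 1e4), seed = 5)
  v <- simulate_genotype_matrix(cfg)$sv$variants
  for (ch in unique(v$chrom)) {
    vc <- v[v$chrom == ch, ]
    vc <- vc[order(vc$pos), ]
    expect_true(all(vc$pos[-1] > vc$end[-nrow(vc)]))
    expect_true(all(vc$end <= cfg$chrom_lengths[[ch]]))
  }
  expect_true(all(abs(v$svlen) >= 1e3 & abs(v$svlen) <= 1e4))
  expect_true(all(v$end - v$pos + 1 == abs(v$svlen)))
})

test_that("within-group genotypes are Hardy-Weinberg (no systematic het excess)", {
  cfg <- sim_config(n_variants = 300, target_fst = 0, missing_rate = 0,
                    chrom_lengths = c(chr1 = 2e7), len_range = c(1e3, 5e3),
                    seed = 13)
  sim <- simulate_genotype_matrix(cfg)
  g <- sim$sv$geno[, sim$sv$panel$group == "HL"]
  p_excess <- vapply(seq_len(nrow(g)), function(i) {
    exc_het_pvalue(sum(g[i, ] == 0), sum(g[i, ] == 1), sum(g[i, ] == 2))
  }, numeric(1))
  ## under HWE the one-sided excess p is super-uniform: P(p < 0.05) <= 0.05
  expect_lt(mean(p_excess < 0.05), 0.08)
})

test_that("a fixed-difference sweep yields per-site FST of 1 at every sweep site", {
  cfg <- sim_config(n_variants = 200, chrom_lengths = c(chr1 = 1e7),
                    len_range = c(1e3, 3e3), target_fst = 0.02,
                    missing_rate = 0,
                    sweep = sweep_spec("chr1", 4e6, 4.5e6, hl_freq = 1, ll_freq = 0),
                    seed = 17)
  sim <- simulate_genotype_matrix(cfg)
  expect_gt(sum(sim$truth$in_sweep), 0)
  comp <- cnvselscan:::site_components(sim$sv)
  ratio <- comp[, "a"] / rowSums(comp)
  expect_true(all(ratio[sim$truth$in_sweep] == 1))
})

test_that("sweep specifications outside the genome are rejected", {
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e6),
                          sweep = sweep_spec("chr2", 1, 1000, 1, 0)),
               "not in chrom_lengths")
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e6),
                          sweep = sweep_spec("chr1", 5e5, 2e6, 1, 0)),
               "beyond")
  expect_error(sweep_spec("chr1", 100, 50, 1, 0), "start")
  expect_error(sweep_spec("chr1", 1, 100, 1.2, 0), "frequencies")
})

test_that("fragment_to_callsets round-trips through merging at zero jitter and dropout", {
  cfg <- sim_config(n_variants = 50, chrom_lengths = c(chr1 = 5e6),
                    len_range = c(2e3, 1e4), missing_rate = 0, seed = 31)
  sim <- simulate_genotype_matrix(cfg)
  carried <- rowSums(sim$sv$geno >= 1, na.rm = TRUE) > 0
  truth <- cnvselscan:::subset_sv(sim$sv, carried)
  cs <- fragment_to_callsets(sim$sv, jitter_bp = 0, dropout = 0, seed = 1)
  merged <- merge_population(cs)$sv
  expect_equal(nrow(merged$variants), nrow(truth$variants))
  expect_equal(merged$variants$pos, truth$variants$pos)
  expect_equal(merged$variants$end, truth$variants$end)
  expect_identical(unname(merged$geno), unname(truth$geno))
})

test_that("jittered copies of one deletion stay nearly identical intervals", {
  panel <- make_panel(15, 15)
  sv <- make_sv(matrix(1L, 1, 30), panel, pos = 100000, len = 10000)
  cs <- fragment_to_callsets(sv, jitter_bp = 100, dropout = 0, seed = 3)
  v <- cs$variants
  expect_equal(nrow(v), 30)
  ro <- combn(nrow(v), 2, function(ij) {
    reciprocal_overlap(c(v$pos[ij[1]], v$end[ij[1]]),
                       c(v$pos[ij[2]], v$end[ij[2]]))
  })
  expect_true(all(ro >= 0.98))
})

test_that("full dropout empties the callsets", {
  cfg <- sim_config(n_variants = 20, chrom_lengths = c(chr1 = 2e6),
                    len_range = c(1e3, 2e3), seed = 41)
  sim <- simulate_genotype_matrix(cfg)
  cs <- fragment_to_callsets(sim$sv, jitter_bp = 10, dropout = 1, seed = 2)
  expect_equal(n_variants(cs), 0)
})

test_that("simulate_annotation places the requested gene territory deterministically", {
  ann1 <- simulate_annotation(c(chr1 = 1e6), 10, gene_length = 20000, seed = 9)
  ann2 <- simulate_annotation(c(chr1 = 1e6), 10, gene_length = 20000, seed = 9)
  expect_identical(ann1, ann2)
  bodies <- gene_bodies(ann1)
  expect_equal(nrow(bodies), 10)
  expect_equal(sum(bodies$end - bodies$start + 1) / 1e6, 0.2)
  bodies <- bodies[order(bodies$start), ]
  expect_true(all(bodies$start[-1] > bodies$end[-nrow(bodies)]))
  ## gff3 round trip preserves the annotation
  path <- tempfile(fileext = ".gff3")
  write_gene_annotation(ann1, path)
  back <- read_gene_annotation(path)
  expect_equal(sort(unique(back$gene_id)), sort(unique(ann1$gene_id)))
  for (k in c("gene", "ncRNA_gene", "CDS", "five_prime_UTR")) {
    expect_equal(sum(back$feature_kind == k), sum(ann1$feature_kind == k))
  }
})

test_that("an empty annotation classifies every CNV as intergenic", {
  ann <- simulate_annotation(c(chr1 = 1e6), 0, seed = 1)
  sv <- make_sv(matrix(1L, 3, 10), pos = c(1e4, 2e5, 5e5))
  calls <- classify_features(sv, ann)
  expect_true(all(calls$category == "intergenic"))
  expect_true(all(calls$genes == ""))
})

test_that("simulate_annotation refuses an overfull genome", {
  expect_error(simulate_annotation(c(chr1 = 1e5), 10, gene_length = 20000),
               "too small")
})
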