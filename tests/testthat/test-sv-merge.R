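test_that("reciprocal overlap follows the min-over-both-lengths definition", {
  expect_equal(reciprocal_overlap(c(100, 199), c(150, 249)), 0.5)
  expect_equal(reciprocal_overlap(c(100, 199), c(100, 199)), 1.0)
  expect_equal(reciprocal_overlap(c(100, 199), c(300, 399)), 0.0)
  ## asymmetric lengths: shared 50 of 100 vs 50 of 200
  expect_equal(reciprocal_overlap(c(100, 199), c(150, 349)), 0.25)
  expect_error(reciprocal_overlap(c(100, 99), c(1, 10)), "length")
})

test_that("genotype concordance counts only samples called in both records", {
  g29 <- c(rep(0L, 15), rep(1L, 14), 2L)
  g30 <- c(rep(0L, 15), rep(1L, 15))
  expect_equal(genotype_concordance(g30, g29), 29 / 30)
  expect_equal(genotype_concordance(g30, g30), 1.0)
  a <- c(rep(0L, 9), 1L, rep(NA_integer_, 20))
  b <- c(rep(0L, 9), 2L, rep(NA_integer_, 20))
  expect_equal(genotype_concordance(a, b), 0.9)
  expect_equal(genotype_concordance(rep(NA_integer_, 5), rep(NA_integer_, 5)), 1.0)
})

test_that("overlap thresholds flip the merge decision exactly at the printed bounds", {
  panel <- make_panel(5, 5)
  g <- matrix(rep(c(0L, 1L), each = 5), 2, 10, byrow = TRUE)
  g <- rbind(g[1, ], g[1, ])  # identical genotypes, concordance 1
  ## DEL pair at reciprocal overlap 0.49: [1,100] vs [52,151] -> 49/100
  del49 <- make_sv(g, panel, pos = c(1, 52), len = 100)
  expect_equal(n_variants(merge_population(del49)$sv), 2)
  ## 0.50: [1,100] vs [51,150] -> 50/100
  del50 <- make_sv(g, panel, pos = c(1, 51), len = 100)
  expect_equal(n_variants(merge_population(del50)$sv), 1)
  ## DUP at 0.89 vs 0.90: [1,1000] vs [112,1111] -> 889/1000; [101,1100] -> 900/1000
  dup89 <- make_sv(g, panel, pos = c(1, 112), len = 1000, svtype = "DUP")
  expect_equal(n_variants(merge_population(dup89)$sv), 2)
  dup90 <- make_sv(g, panel, pos = c(1, 101), len = 1000, svtype = "DUP")
  expect_equal(n_variants(merge_population(dup90)$sv), 1)
  ## a DEL at 0.85 overlap merges while a DUP at 0.85 does not
  mix85 <- make_sv(g, panel, pos = c(1, 151), len = 1000, svtype = "DUP")
  expect_equal(n_variants(merge_population(mix85)$sv), 2)
  del85 <- make_sv(g, panel, pos = c(1, 151), len = 1000, svtype = "DEL")
  expect_equal(n_variants(merge_population(del85)$sv), 1)
})

test_that("genotype concordance 29/30 merges but 28/30 does not", {
  panel <- make_panel(15, 15)
  base <- rep(c(0L, 1L, 2L), 10)
  g29 <- base; g29[1] <- 1L
  g28 <- base; g28[1] <- 1L; g28[2] <- 2L
  sv29 <- make_sv(rbind(base, g29), panel, pos = c(1000, 1000), len = 500)
  expect_equal(n_variants(merge_population(sv29)$sv), 1)
  sv28 <- make_sv(rbind(base, g28), panel, pos = c(1000, 1000), len = 500)
  expect_equal(n_variants(merge_population(sv28)$sv), 2)
})

test_that("single-linkage chains merge records whose direct overlap is sub-threshold", {
  panel <- make_panel(5, 5)
  g <- matrix(0L, 3, 10); g[, 1] <- 1L
  ## A [1,1000], B [401,1400], C [801,1800]: A~B 0.6, B~C 0.6, A~C 0.2
  sv <- make_sv(g, panel, pos = c(1, 401, 801), len = 1000)
  m <- merge_population(sv)
  expect_equal(n_variants(m$sv), 1)
  expect_equal(m$sv$variants$support, 3)
  ## representative takes the member-wise lower-median breakpoints
  expect_equal(m$sv$variants$pos, 401)
  expect_equal(m$sv$variants$end, 1400)
})

test_that("merging is idempotent and invariant to input order", {
  cfg <- sim_config(n_variants = 40, chrom_lengths = c(chr1 = 2e6),
                    len_range = c(2e3, 8e3), missing_rate = 0.05, seed = 19)
  sim <- simulate_genotype_matrix(cfg)
  cs <- fragment_to_callsets(sim$sv, jitter_bp = 200, dropout = 0.1, seed = 5)
  m1 <- merge_population(cs)$sv
  m1$variants$support <- NULL; m1$variants$members <- NULL
  m2 <- merge_population(m1)$sv
  expect_equal(m2$variants$pos, m1$variants$pos)
  expect_equal(m2$variants$end, m1$variants$end)
  expect_identical(unname(m2$geno), unname(m1$geno))
  ## permute the input records
  perm <- withr::with_seed(1, sample(n_variants(cs)))
  csp <- cnvselscan:::subset_sv(cs, perm)
  mp <- merge_population(csp)$sv
  expect_equal(mp$variants$pos, m1$variants$pos)
  expect_equal(mp$variants$members, merge_population(cs)$sv$variants$members)
})

test_that("merge clusters equal brute-force connected components of the pair predicate", {
  th <- merge_thresholds()
  for (seed in 1:4) {
    sv <- withr::with_seed(seed, {
      n <- 50
      panel <- make_panel(5, 5)
      pos <- sort(sample.int(50000, n))
      len <- sample(500:5000, n, replace = TRUE)
      g <- matrix(sample(c(0L, 1L, 2L, NA), n * 10, replace = TRUE,
                         prob = c(0.5, 0.3, 0.15, 0.05)), n, 10)
      make_sv(g, panel, pos = pos, len = len)
    })
    m <- merge_population(sv, th)
    v <- sv$variants
    pred <- function(i, j) {
      ro <- reciprocal_overlap(c(v$pos[i], v$end[i]), c(v$pos[j], v$end[j]))
      ro >= th$del_overlap &&
        genotype_concordance(sv$geno[i, ], sv$geno[j, ]) >= th$gt_consistency
    }
    comp <- brute_components(n_variants(sv), pred)
    expect_equal(n_variants(m$sv), length(unique(comp)))
    ## member partitions agree
    got <- sort(vapply(split(v$id, comp), function(ids) {
      paste(sort(ids), collapse = ",")
    }, character(1)))
    expect_equal(sort(m$sv$variants$members), unname(got))
  }
})

test_that("insertions merge by breakpoint distance and length ratio", {
  panel <- make_panel(5, 5)
  g <- matrix(0L, 2, 10); g[, 2] <- 2L
  near <- make_sv(g, panel, pos = c(5000, 5080), len = c(400, 380), svtype = "INS")
  expect_equal(n_variants(merge_population(near)$sv), 1)
  far <- make_sv(g, panel, pos = c(5000, 5200), len = c(400, 380), svtype = "INS")
  expect_equal(n_variants(merge_population(far)$sv), 2)
  shortlong <- make_sv(g, panel, pos = c(5000, 5080), len = c(400, 100), svtype = "INS")
  expect_equal(n_variants(merge_population(shortlong)$sv), 2)
})

test_that("different chromosomes and different SV types never merge", {
  panel <- make_panel(5, 5)
  g <- matrix(0L, 2, 10); g[, 1] <- 1L
  cross_chrom <- make_sv(g, panel, pos = c(1000, 1000), len = 500,
                         chrom = c("chr1", "chr2"))
  expect_equal(n_variants(merge_population(cross_chrom)$sv), 2)
  cross_type <- make_sv(g, panel, pos = c(1000, 1000), len = 500,
                        svtype = c("DEL", "DUP"))
  expect_equal(n_variants(merge_population(cross_type)$sv), 2)
})

test_that("majority-vote representative genotypes fall back to missing on ties", {
  panel <- make_panel(2, 2)
  g <- rbind(c(0L, 1L, 2L, NA), c(0L, 2L, 2L, NA), c(0L, 1L, 0L, 1L))
  sv <- make_sv(g, panel, pos = c(100, 100, 100), len = 200)
  ## relaxed concordance so the deliberately discordant columns still cluster
  m <- merge_population(sv, merge_thresholds(gt_consistency = 0.5))$sv
  expect_equal(n_variants(m), 1)
  ## col1: unanimous 0; col2: 1/2/1 -> 1; col3: 2/2/0 -> 2; col4: NA/NA/1 -> NA
  expect_equal(unname(m$geno[1, ]), c(0L, 1L, 2L, NA))
})
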