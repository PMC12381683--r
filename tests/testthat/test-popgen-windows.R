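test_that("per-site Weir-Cockerham components match the longhand oracle on worked examples", {
  ## fixed difference between the groups
  comp <- site_wc_components(rbind(c(0, 0, 15), c(15, 0, 0)))
  expect_equal(comp, wc_oracle(c(0, 0, 15), c(15, 0, 0)), tolerance = 1e-14)
  expect_equal(unname(comp["a"] / sum(comp)), 1.0)
  ## identical genotype counts: no among-population variance, estimate <= 0
  comp2 <- site_wc_components(rbind(c(7, 6, 2), c(7, 6, 2)))
  expect_equal(comp2, wc_oracle(c(7, 6, 2), c(7, 6, 2)), tolerance = 1e-14)
  expect_lte(unname(comp2["a"] / sum(comp2)), 0)
  ## monomorphic site is unusable
  expect_true(all(is.na(site_wc_components(rbind(c(15, 0, 0), c(15, 0, 0))))))
  ## a group with no called genotype is unusable
  expect_true(all(is.na(site_wc_components(rbind(c(0, 0, 0), c(5, 5, 5))))))
})

test_that("vectorised components equal the longhand oracle on random sites", {
  set.seed(42)
  for (k in 1:500) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    c1 <- as.vector(stats::rmultinom(1, n1, runif(3)))
    c2 <- as.vector(stats::rmultinom(1, n2, runif(3)))
    got <- site_wc_components(rbind(c1, c2))
    want <- wc_oracle(c1, c2)
    if (sum(want) == 0) {
      expect_true(all(is.na(got)))
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("site_pi equals the brute-force mean pairwise difference", {
  expect_equal(site_pi(4, 2), 2 / 3)
  expect_equal(site_pi(4, 0), 0)
  expect_equal(site_pi(2, 1), 1.0)
  expect_true(is.na(site_pi(1, 0)))
  for (n in c(2, 3, 7, 20, 60)) {
    for (alt in 0:n) {
      brute <- alt * (n - alt) / choose(n, 2)
      expect_equal(site_pi(n, alt), brute, tolerance = 1e-14)
    }
  }
})

test_that("the window grid tiles each chromosome with clipped trailing windows", {
  grid <- window_grid(1e5, 1e4, c(chr1 = 1e6, chr2 = 250001))
  w <- build_windows(grid)
  expect_equal(sum(w$chrom == "chr1"), 100)
  expect_equal(sum(w$chrom == "chr2"), 26)
  w1 <- w[w$chrom == "chr1", ]
  expect_equal(w1$start[1], 1)
  expect_equal(diff(w1$start), rep(1e4, 99))
  expect_true(all(w1$end == pmin(w1$start + 1e5 - 1, 1e6)))
  ## the last full-size window and the clipped tail
  expect_equal(w1$end[91], 1e6)
  expect_equal(w1$end[100], 1e6)
  expect_lt(w1$end[100] - w1$start[100] + 1, 1e5)
  expect_error(window_grid(1e4, 1e5, c(chr1 = 1e6)), "step")
})

test_that("each site contributes to exactly the windows containing its start position", {
  grid <- window_grid(1e5, 1e4, c(chr1 = 1e6))
  amap <- cnvselscan:::assign_windows("chr1", 250000, grid)
  w <- build_windows(grid)
  expect_true(all(w$start[amap$window] <= 250000 & w$end[amap$window] >= 250000))
  expect_equal(nrow(amap), 10)  # interior positions sit in window_size/step windows
  ## positions near the chromosome start fall in fewer windows
  expect_equal(nrow(cnvselscan:::assign_windows("chr1", 5000, grid)), 1)
})

test_that("windowed FST is the ratio of summed components", {
  panel <- make_panel(15, 15)
  g <- rbind(
    geno_row(c(0, 0, 15), c(15, 0, 0)),   # fixed difference
    geno_row(c(7, 6, 2), c(7, 6, 2))      # no divergence
  )
  sv <- make_sv(g, panel, pos = c(20000, 30000), len = 100)
  grid <- window_grid(1e5, 1e5, c(chr1 = 1e5))
  wf <- windowed_fst(sv, grid)
  expect_equal(nrow(wf), 1)
  c1 <- wc_oracle(c(0, 0, 15), c(15, 0, 0))
  c2 <- wc_oracle(c(7, 6, 2), c(7, 6, 2))
  want <- (c1["a"] + c2["a"]) / (sum(c1) + sum(c2))
  expect_equal(wf$fst, unname(want), tolerance = 1e-12)
  ## strictly between the two per-site ratios
  expect_gt(wf$fst, c2["a"] / sum(c2))
  expect_lt(wf$fst, 1)
  ## a single-site window equals the per-site ratio
  solo <- make_sv(g[1, , drop = FALSE], panel, pos = 20000, len = 100)
  expect_equal(windowed_fst(solo, grid)$fst, unname(c1["a"] / sum(c1)))
})

test_that("windowed pi divides by the genomic span and empty windows are zero", {
  panel <- make_panel(2, 2)
  ## HL: 4 alleles with 2 alt -> site pi = 2/3
  g <- matrix(c(1L, 1L, 0L, 0L), 1, 4)
  sv <- make_sv(g, panel, pos = 50000, len = 100)
  grid <- window_grid(1e5, 1e5, c(chr1 = 2e5))
  pw <- windowed_pi(sv, "HL", grid)
  expect_equal(pw$pi[1], (2 / 3) / 1e5, tolerance = 1e-12)
  expect_equal(pw$pi[2], 0)
  ## clipped window divides by its actual span
  grid2 <- window_grid(1e5, 1e5, c(chr1 = 75000))
  pw2 <- windowed_pi(sv, "HL", grid2)
  expect_equal(pw2$pi[1], (2 / 3) / 75000, tolerance = 1e-12)
})

test_that("log2 diversity ratio is defined only when both diversities are positive", {
  expect_equal(log2_pi_ratio(0.002, 0.001), 1.0)
  expect_equal(log2_pi_ratio(0.004, 0.004), 0.0)
  expect_true(is.na(log2_pi_ratio(0.0, 0.001)))
  expect_true(is.na(log2_pi_ratio(0.001, 0.0)))
  expect_true(is.na(log2_pi_ratio(0, 0)))
})

test_that("window statistics stay within their theoretical bounds on simulated data", {
  cfg <- sim_config(n_variants = 600, chrom_lengths = c(chr1 = 6e6),
                    len_range = c(500, 2e3), target_fst = 0.1, seed = 23)
  sim <- simulate_genotype_matrix(cfg)
  ws <- window_stats(sim$sv, window_grid(1e5, 1e4, c(chr1 = 6e6)))
  expect_true(all(ws$fst[is.finite(ws$fst)] <= 1))
  expect_true(all(ws$pi_hl >= 0 & ws$pi_ll >= 0))
  expect_true(all(is.na(ws$log2_ratio) | is.finite(ws$log2_ratio)))
  expect_true(all(is.na(ws$fst[ws$n_sites == 0])))
})

test_that("an undifferentiated cohort has near-zero mean windowed FST", {
  cfg <- sim_config(n_variants = 2000, chrom_lengths = c(chr1 = 2e7),
                    len_range = c(500, 2e3), target_fst = 0,
                    missing_rate = 0, seed = 29)
  sim <- simulate_genotype_matrix(cfg)
  ws <- windowed_fst(sim$sv, window_grid(1e5, 1e4, c(chr1 = 2e7)))
  expect_equal(mean(ws$fst, na.rm = TRUE), 0, tolerance = 0.01)
  expect_equal(genomewide_fst(sim$sv), 0, tolerance = 0.01)
})

test_that("a monomorphic group in a sweep region drives its windowed pi to zero", {
  cfg <- sim_config(n_variants = 800, chrom_lengths = c(chr1 = 1e7),
                    len_range = c(500, 2e3), target_fst = 0.02,
                    sweep = sweep_spec("chr1", 4e6, 4.4e6, hl_freq = 1, ll_freq = 0.5),
                    seed = 37)
  sim <- simulate_genotype_matrix(cfg)
  grid <- window_grid(1e5, 1e4, c(chr1 = 1e7))
  ws <- window_stats(sim$sv, grid)
  inside <- ws$start >= 4e6 & ws$end <= 4.4e6
  outside <- ws$end < 3.8e6 | ws$start > 4.6e6
  expect_equal(max(ws$pi_hl[inside]), 0)
  expect_gt(mean(ws$pi_ll[inside]), 0)
  expect_gt(mean(ws$pi_hl[outside & ws$n_sites > 0]), 0)
})
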