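## Independent oracles used by the tests. Each re-derives its quantity by a
## different route than the package (longhand scalar algebra, exhaustive
## enumeration, brute-force graph search) so that agreement is informative.

## Weir & Cockerham (1984) variance components, scalar longhand version
## written directly from the multi-population definitions with explicit sums.
## counts_i = c(n_hom_ref, n_het, n_hom_alt) for population i.
wc_oracle <- function(counts1, counts2) {
  n <- c(sum(counts1), sum(counts2))
  p <- c((counts1[2] + 2 * counts1[3]) / (2 * n[1]),
         (counts2[2] + 2 * counts2[3]) / (2 * n[2]))
  h <- c(counts1[2] / n[1], counts2[2] / n[2])
  r <- 2
  nbar <- mean(n)
  s2 <- 0
  pbar <- 0
  hbar <- 0
  for (i in 1:r) pbar <- pbar + n[i] * p[i] / (r * nbar)
  for (i in 1:r) s2 <- s2 + n[i] * (p[i] - pbar)^2 / ((r - 1) * nbar)
  for (i in 1:r) hbar <- hbar + n[i] * h[i] / (r * nbar)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

## exact excess-het p-value by direct log-factorial enumeration of every
## heterozygote count compatible with the allele counts
exchet_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  n_major <- 2 * n - n_minor
  hs <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  logw <- vapply(hs, function(h) {
    naa <- (n_minor - h) / 2
    nbb <- (n_major - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb)
  }, numeric(1))
  w <- exp(logw - max(logw))
  prob <- w / sum(w)
  sum(prob[hs >= n_het])
}

## two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
## tables with the observed margins (standard sum of probabilities <= observed,
## with the conventional (1 + 1e-7) tie tolerance)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

## longhand 2x2 Pearson chi-square with optional Yates correction
chisq_oracle <- function(tab, correct = TRUE) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - E)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / E)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

## brute-force connected components of an explicit pairwise predicate
brute_components <- function(n, pred) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && pred(i, j)) adj[i, j] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

## brute-force feature classifier: per-variant loops over plain intervals,
## testing every category predicate independently then applying precedence
brute_classify <- function(variant, ann, flank_bp = 1000) {
  ovl <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1
  hit_kind <- function(kinds) {
    any(vapply(seq_len(nrow(ann)), function(i) {
      ann$feature_kind[i] %in% kinds && ann$chrom[i] == variant$chrom &&
        ovl(variant$pos, variant$end, ann$start[i], ann$end[i])
    }, logical(1)))
  }
  exons <- ann[ann$feature_kind %in% c("exon", "ncRNA_exon"), , drop = FALSE]
  splice_hit <- FALSE
  for (gid in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) next
    for (k in seq_len(nrow(ex) - 1)) {
      is_ <- ex$end[k] + 1
      ie <- ex$start[k + 1] - 1
      if (ie < is_) next
      for (ss in list(c(is_, min(ie, is_ + 1)), c(max(is_, ie - 1), ie))) {
        if (ex$chrom[1] == variant$chrom && ovl(variant$pos, variant$end, ss[1], ss[2])) {
          splice_hit <- TRUE
        }
      }
    }
  }
  bodies <- ann[ann$feature_kind %in% c("gene", "ncRNA_gene"), , drop = FALSE]
  up_hit <- down_hit <- FALSE
  for (i in seq_len(nrow(bodies))) {
    if (bodies$chrom[i] != variant$chrom) next
    left <- c(max(1, bodies$start[i] - flank_bp), bodies$start[i] - 1)
    right <- c(bodies$end[i] + 1, bodies$end[i] + flank_bp)
    up <- if (bodies$strand[i] == "+") left else right
    down <- if (bodies$strand[i] == "+") right else left
    if (up[2] >= up[1] && ovl(variant$pos, variant$end, up[1], up[2])) up_hit <- TRUE
    if (down[2] >= down[1] && ovl(variant$pos, variant$end, down[1], down[2])) down_hit <- TRUE
  }
  if (hit_kind("CDS")) return("exonic")
  if (splice_hit && !hit_kind(c("exon", "ncRNA_exon"))) return("splicing")
  if (hit_kind("five_prime_UTR")) return("UTR5")
  if (hit_kind("three_prime_UTR")) return("UTR3")
  if (hit_kind("ncRNA_exon")) return("ncRNA_exonic")
  if (hit_kind("ncRNA_gene")) return("ncRNA_intronic")
  if (hit_kind("gene")) return("intronic")
  if (up_hit && down_hit) return("upstream_and_downstream")
  if (up_hit) return("upstream")
  if (down_hit) return("downstream")
  "intergenic"
}

## double-loop VanRaden GRM oracle
grm_oracle <- function(geno) {
  X <- t(geno)                        # samples x variants
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  ns <- nrow(X)
  G <- matrix(0, ns, ns)
  denom <- 2 * sum(p * (1 - p))
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      acc <- 0
      for (k in seq_along(p)) {
        xi <- if (is.na(X[i, k])) 2 * p[k] else X[i, k]
        xj <- if (is.na(X[j, k])) 2 * p[k] else X[j, k]
        acc <- acc + (xi - 2 * p[k]) * (xj - 2 * p[k])
      }
      G[i, j] <- acc / denom
    }
  }
  G
}
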