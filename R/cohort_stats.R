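#' Per-group deletion-allele frequencies
#'
#' Alternate (deletion) allele frequency per variant and group, over
#' non-missing alleles. A group with every genotype missing at a variant
#' gets `NA` there and is excluded from that group's frequency spectrum.
#'
#' @param sv an [sv_set].
#' @return `data.frame` with `id`, `freq_hl`, `freq_ll`.
#' @export
group_frequencies <- function(sv) {
  freq <- function(which) {
    g <- group_geno(sv, which)
    n <- rowSums(!is.na(g))
    ifelse(n > 0, rowSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  }
  data.frame(id = sv$variants$id, freq_hl = freq("HL"), freq_ll = freq("LL"),
             stringsAsFactors = FALSE)
}

#' Per-group allele-frequency spectrum
#'
#' Counts of variants per allele-frequency bin and group. Bins are half-open
#' `[x, x + 0.1)` on 0-1 in 0.1 steps, with the last bin closed at 1.
#'
#' @param freqs output of [group_frequencies] (or an [sv_set]).
#' @return A list of class `frequency_spectrum`: `bin_start`, `bin_end`,
#'   `counts_hl`, `counts_ll`, plus per-group counts of variants excluded
#'   for having no called genotype.
#' @export
frequency_spectrum <- function(freqs) {
  if (inherits(freqs, "sv_set")) freqs <- group_frequencies(freqs)
  bin_of <- function(f) pmin(floor(f * 10), 9) + 1
  count <- function(f) {
    f <- f[!is.na(f)]
    tabulate(bin_of(f), nbins = 10)
  }
  structure(list(
    bin_start = seq(0, 0.9, by = 0.1), bin_end = seq(0.1, 1, by = 0.1),
    counts_hl = count(freqs$freq_hl), counts_ll = count(freqs$freq_ll),
    excluded_hl = sum(is.na(freqs$freq_hl)),
    excluded_ll = sum(is.na(freqs$freq_ll))
  ), class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat("<frequency_spectrum>\n")
  print(data.frame(bin = sprintf("[%.1f,%.1f%s", x$bin_start, x$bin_end,
                                 c(rep(")", 9), "]")),
                   HL = x$counts_hl, LL = x$counts_ll))
  invisible(x)
}

#' Per-chromosome CNV distribution tests
#'
#' For each chromosome, a 2x2 chi-square test of CNV presence on versus off
#' that chromosome between the groups, where a variant counts as present in
#' a group when the group carries at least one alternate allele. Yates
#' continuity correction is applied by default; p-values are
#' Bonferroni-corrected by the number of chromosomes actually tested
#' (chromosomes with no presence in either group are skipped).
#'
#' @param sv an [sv_set].
#' @param alpha significance level for the corrected p-values.
#' @param correct apply Yates continuity correction (default `TRUE`).
#' @return `data.frame` with per-chromosome counts, `chi2`, `p`,
#'   `p_bonferroni` and `significant`.
#' @export
chrom_distribution_tests <- function(sv, alpha = 0.05, correct = TRUE) {
  present <- function(which) {
    g <- group_geno(sv, which)
    rowSums(g, na.rm = TRUE) >= 1
  }
  pres_hl <- present("HL")
  pres_ll <- present("LL")
  chroms <- unique(sv$variants$chrom)
  on_hl <- vapply(chroms, function(ch) sum(pres_hl[sv$variants$chrom == ch]), numeric(1))
  on_ll <- vapply(chroms, function(ch) sum(pres_ll[sv$variants$chrom == ch]), numeric(1))
  tot_hl <- sum(pres_hl)
  tot_ll <- sum(pres_ll)
  tested <- on_hl + on_ll > 0
  res <- data.frame(chrom = chroms, n_hl = on_hl, n_ll = on_ll,
                    chi2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in which(tested)) {
    tab <- rbind(c(on_hl[i], tot_hl - on_hl[i]),
                 c(on_ll[i], tot_ll - on_ll[i]))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    res$chi2[i] <- unname(ht$statistic)
    res$p[i] <- ht$p.value
  }
  n_tests <- sum(tested)
  res$p_bonferroni <- pmin(1, res$p * n_tests)
  res$significant <- !is.na(res$p_bonferroni) & res$p_bonferroni < alpha
  rownames(res) <- NULL
  res
}

#' Fisher exact tests on frequency-spectrum bins
#'
#' Per bin, a two-sided Fisher exact test on the 2x2 table of in-bin versus
#' out-of-bin variant counts by group. A bin empty in both groups gets
#' p = 1 by convention.
#'
#' @param spectrum a [frequency_spectrum].
#' @return `data.frame` with `bin_start`, `bin_end`, per-group counts,
#'   `odds_ratio` and `p`.
#' @export
bin_fisher_tests <- function(spectrum) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  tot_hl <- sum(spectrum$counts_hl)
  tot_ll <- sum(spectrum$counts_ll)
  if (tot_hl + tot_ll == 0) stop("empty spectrum")
  out <- data.frame(bin_start = spectrum$bin_start, bin_end = spectrum$bin_end,
                    n_hl = spectrum$counts_hl, n_ll = spectrum$counts_ll,
                    odds_ratio = NA_real_, p = NA_real_)
  for (i in seq_len(10)) {
    a <- spectrum$counts_hl[i]
    c_ <- spectrum$counts_ll[i]
    if (a + c_ == 0) {
      out$p[i] <- 1
      next
    }
    tab <- rbind(c(a, tot_hl - a), c(c_, tot_ll - c_))
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    out$odds_ratio[i] <- unname(ht$estimate)
    out$p[i] <- ht$p.value
  }
  out
}

#' Genetic relationship matrix from CNV dosages
#'
#' VanRaden-style GRM: dosages are mean-imputed at missing entries, centred
#' by twice the allele frequency, and the cross-product is scaled by
#' `2 * sum(p (1 - p))` over the polymorphic variants used.
#'
#' @param sv an [sv_set].
#' @return Symmetric samples-by-samples numeric matrix.
#' @export
compute_grm <- function(sv) {
  X <- t(sv$geno)                      # samples x variants
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic variants")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  for (j in seq_along(p)) {
    X[is.na(X[, j]), j] <- 2 * p[j]
  }
  Z <- sweep(X, 2, 2 * p)
  (Z %*% t(Z)) / (2 * sum(p * (1 - p)))
}

#' PCA of population structure from the GRM
#'
#' Eigendecomposition of [compute_grm]; sample coordinates are the top
#' eigenvectors scaled by the square root of their eigenvalues. Signs are
#' fixed deterministically (the largest-magnitude loading of each component
#' is positive).
#'
#' @param sv an [sv_set] with at least two samples and one polymorphic
#'   variant.
#' @param n_components number of components to return (default 2).
#' @return A list of class `grm_pca` with `scores` (data.frame: sample,
#'   group, PC1...), `varexp` (fraction of variance per component) and
#'   `grm`.
#' @export
grm_pca <- function(sv, n_components = 2) {
  if (nrow(sv$panel) < 2) stop("need at least two samples")
  G <- compute_grm(sv)
  eig <- eigen(G, symmetric = TRUE)
  k <- min(n_components, ncol(G))
  vals <- pmax(eig$values, 0)
  scores <- sapply(seq_len(k), function(j) {
    v <- eig$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    v * sqrt(vals[j])
  })
  scores <- matrix(scores, ncol = k,
                   dimnames = list(NULL, paste0("PC", seq_len(k))))
  structure(list(
    scores = cbind(data.frame(sample_id = sv$panel$sample_id,
                              group = sv$panel$group,
                              stringsAsFactors = FALSE),
                   as.data.frame(scores)),
    varexp = vals[seq_len(k)] / sum(vals),
    grm = G
  ), class = "grm_pca")
}
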