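#' Sliding-window grid
#'
#' Windows of `window_size` bp advanced by `step` bp: on each chromosome the
#' starts are 1, 1 + step, 1 + 2*step, ... while the start lies on the
#' chromosome, and the last windows are clipped at the chromosome end.
#'
#' @param window_size window span in bp (default 100 kb).
#' @param step advance in bp (default 10 kb); must not exceed `window_size`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return A list of class `window_grid`.
#' @export
window_grid <- function(window_size = 1e5, step = 1e4, chrom_lengths) {
  if (step > window_size) stop("step must be <= window_size")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 chrom_lengths = chrom_lengths),
            class = "window_grid")
}

#' Materialise the windows of a grid
#'
#' @param grid a [window_grid].
#' @return `data.frame` with `chrom`, `start`, `end` (clipped), ordered by
#'   chromosome then start.
#' @export
build_windows <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  out <- lapply(names(grid$chrom_lengths), function(ch) {
    L <- grid$chrom_lengths[[ch]]
    starts <- seq.int(1L, L, by = grid$step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + grid$window_size - 1L, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## map site positions to window row indices of build_windows(grid);
## membership: a site belongs to a window iff its POS lies in [start, end]
assign_windows <- function(chrom, pos, grid) {
  chroms <- names(grid$chrom_lengths)
  offsets <- cumsum(c(0, vapply(chroms, function(ch) {
    length(seq.int(1L, grid$chrom_lengths[[ch]], by = grid$step))
  }, numeric(1))))
  names(offsets) <- c(chroms, "total")
  ws <- grid$window_size; st <- grid$step
  pieces <- lapply(intersect(unique(chrom), chroms), function(ch) {
    sel <- which(chrom == ch)
    p <- pos[sel]
    kmax_chrom <- floor((grid$chrom_lengths[[ch]] - 1) / st)
    kmin <- pmax(0, ceiling((p - ws) / st))
    kmax <- pmin(floor((p - 1) / st), kmax_chrom)
    cnt <- pmax(0L, as.integer(kmax - kmin + 1))
    ks <- sequence(cnt) - 1L + rep.int(kmin, cnt)
    data.frame(site = rep.int(sel, cnt),
               window = offsets[[ch]] + ks + 1L)
  })
  if (length(pieces) == 0) return(data.frame(site = integer(0), window = integer(0)))
  do.call(rbind, pieces)
}

## per-site per-group summaries: sample size, alt frequency, observed het
site_group_summary <- function(sv, which) {
  g <- group_geno(sv, which)
  n <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  het <- rowSums(g == 1L, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
       h = ifelse(n > 0, het / n, NA_real_), alt = alt)
}

## vectorised Weir-Cockerham (1984) variance components for two populations
## of diploids, with the observed-heterozygosity term.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  cbind(a = a, b = b, c = cc)
}

#' Weir-Cockerham variance components for one site
#'
#' Among-population (a), among-individual (b) and within-individual (c)
#' components of the Weir-Cockerham (1984) FST estimator for two diploid
#' populations, computed from genotype counts. The per-site estimate is
#' `a / (a + b + c)`; it may be negative when between-group variance is
#' absent. Sites where a group has no called genotype, where the pooled
#' sample holds fewer than two individuals with data, or where
#' `a + b + c = 0` (monomorphic) are unusable and return `NA` components.
#'
#' @param counts_by_group 2x3 matrix: rows = groups, columns =
#'   `(n_hom_ref, n_het, n_hom_alt)`.
#' @return Named numeric vector `c(a =, b =, c =)`.
#' @export
site_wc_components <- function(counts_by_group) {
  m <- as.matrix(counts_by_group)
  if (!all(dim(m) == c(2, 3))) stop("counts_by_group must be a 2x3 matrix")
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  if (n1 == 0 || n2 == 0 || n1 + n2 < 3) {
    return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  }
  p1 <- (m[1, 2] + 2 * m[1, 3]) / (2 * n1)
  p2 <- (m[2, 2] + 2 * m[2, 3]) / (2 * n2)
  h1 <- m[1, 2] / n1
  h2 <- m[2, 2] / n2
  comp <- wc_components(n1, p1, h1, n2, p2, h2)[1, ]
  if (sum(comp) == 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  comp
}

## all per-site components of an sv_set (NA rows = unusable sites)
site_components <- function(sv) {
  hl <- site_group_summary(sv, "HL")
  ll <- site_group_summary(sv, "LL")
  comp <- wc_components(hl$n, hl$p, hl$h, ll$n, ll$p, ll$h)
  usable <- hl$n > 0 & ll$n > 0 & (hl$n + ll$n) >= 3
  denom <- rowSums(comp)
  usable <- usable & !is.na(denom) & denom != 0
  comp[!usable, ] <- NA_real_
  comp
}

#' Per-site nucleotide diversity
#'
#' Average pairwise difference among `n` sampled alleles with `alt` copies of
#' the alternate allele: `2 * (alt/n) * (1 - alt/n) * n / (n - 1)`, the exact
#' mean over all `C(n, 2)` allele pairs.
#'
#' @param n allele count (>= 2; smaller samples return `NA`).
#' @param alt alternate-allele count, `0 <= alt <= n`. Vectorised.
#' @export
site_pi <- function(n, alt) {
  ifelse(n >= 2, 2 * (alt / n) * (1 - alt / n) * n / (n - 1), NA_real_)
}

#' Windowed weighted FST
#'
#' Ratio-of-sums (weighted) Weir-Cockerham FST per window:
#' `sum(a) / sum(a + b + c)` over usable sites whose start position lies in
#' the window. Windows without a usable site carry `NA` and are excluded
#' from downstream ranking. Negative window values are retained.
#'
#' @param sv a QC-passed [sv_set].
#' @param grid a [window_grid].
#' @return `data.frame`: windows plus `n_sites` and `fst`.
#' @export
windowed_fst <- function(sv, grid) {
  windows <- build_windows(grid)
  comp <- site_components(sv)
  amap <- assign_windows(sv$variants$chrom, sv$variants$pos, grid)
  a <- comp[amap$site, "a"]
  d <- rowSums(comp)[amap$site]
  ok <- !is.na(a)
  sum_a <- rowsum_full(a[ok], amap$window[ok], nrow(windows))
  sum_d <- rowsum_full(d[ok], amap$window[ok], nrow(windows))
  windows$n_sites <- tabulate(amap$window, nbins = nrow(windows))
  windows$fst <- ifelse(sum_d > 0 | sum_d < 0, sum_a / sum_d, NA_real_)
  windows$fst[rowsum_full(rep(1, sum(ok)), amap$window[ok], nrow(windows)) == 0] <- NA_real_
  windows
}

## rowsum over 1..nbins with zeros for empty bins
rowsum_full <- function(x, bin, nbins) {
  out <- numeric(nbins)
  if (length(x)) {
    agg <- rowsum(x, bin)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' Windowed per-group nucleotide diversity
#'
#' Sum of per-site diversity ([site_pi]) of the group's in-window sites,
#' divided by the window's genomic span (clipped windows divide by their
#' actual span). Windows without usable sites return 0.
#'
#' @param sv a QC-passed [sv_set].
#' @param which group, `"HL"` or `"LL"`.
#' @param grid a [window_grid].
#' @return `data.frame`: windows plus `pi` (per-bp diversity).
#' @export
windowed_pi <- function(sv, which, grid) {
  windows <- build_windows(grid)
  s <- site_group_summary(sv, which)
  pis <- site_pi(2 * s$n, s$alt)
  amap <- assign_windows(sv$variants$chrom, sv$variants$pos, grid)
  x <- pis[amap$site]
  ok <- !is.na(x)
  windows$pi <- rowsum_full(x[ok], amap$window[ok], nrow(windows)) /
    (windows$end - windows$start + 1)
  windows
}

#' Log2 diversity-ratio contrast
#'
#' `log2(pi_hl / pi_ll)` where both diversities are positive; `NA` otherwise
#' (such windows are excluded from quantile ranking — a window monomorphic
#' in either group gives no finite contrast).
#'
#' @param pi_hl,pi_ll per-bp window diversities. Vectorised.
#' @export
log2_pi_ratio <- function(pi_hl, pi_ll) {
  ifelse(pi_hl > 0 & pi_ll > 0, log2(pi_hl / pi_ll), NA_real_)
}

#' Per-site selection statistics
#'
#' One row per variant: Weir-Cockerham components and per-site FST (NA for
#' unusable sites) plus per-group site diversity.
#'
#' @param sv an [sv_set].
#' @return `data.frame` with `id`, `chrom`, `pos`, `a`, `b`, `c`, `fst`,
#'   `pi_hl`, `pi_ll`.
#' @export
site_stats <- function(sv) {
  comp <- site_components(sv)
  hl <- site_group_summary(sv, "HL")
  ll <- site_group_summary(sv, "LL")
  data.frame(
    id = sv$variants$id, chrom = sv$variants$chrom, pos = sv$variants$pos,
    a = comp[, "a"], b = comp[, "b"], c = comp[, "c"],
    fst = comp[, "a"] / rowSums(comp),
    pi_hl = site_pi(2 * hl$n, hl$alt),
    pi_ll = site_pi(2 * ll$n, ll$alt),
    stringsAsFactors = FALSE
  )
}

#' Combined per-window selection statistics
#'
#' One row per window with site count, weighted FST, per-group diversity and
#' the log2 diversity ratio — the table every downstream scan consumes.
#'
#' @param sv a QC-passed [sv_set].
#' @param grid a [window_grid].
#' @return `data.frame` with `chrom`, `start`, `end`, `n_sites`, `fst`,
#'   `pi_hl`, `pi_ll`, `log2_ratio`.
#' @export
window_stats <- function(sv, grid) {
  fst <- windowed_fst(sv, grid)
  pi_hl <- windowed_pi(sv, "HL", grid)$pi
  pi_ll <- windowed_pi(sv, "LL", grid)$pi
  fst$pi_hl <- pi_hl
  fst$pi_ll <- pi_ll
  fst$log2_ratio <- log2_pi_ratio(pi_hl, pi_ll)
  fst
}
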