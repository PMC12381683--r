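#' Post-merge QC thresholds
#'
#' The four population filters applied to the merged callset, in this fixed
#' order with first-failing-filter attribution: absolute SV length
#' (`<= 10,000,000` bp), exact excess-heterozygosity p-value (`>= 0.05`),
#' genotype missing rate (`<= 0.2`) and minor allele frequency (strictly
#' `> 0`). Boundary semantics follow the printed inequalities exactly.
#'
#' @param max_abs_svlen maximum absolute SV length in bp.
#' @param min_exchet_p minimum excess-het p-value to retain a site.
#' @param max_f_missing maximum fraction of missing genotypes (inclusive).
#' @param min_maf minor-allele-frequency bound; comparison is strict (`>`).
#' @export
qc_thresholds <- function(max_abs_svlen = 1e7, min_exchet_p = 0.05,
                          max_f_missing = 0.2, min_maf = 0) {
  structure(list(max_abs_svlen = max_abs_svlen, min_exchet_p = min_exchet_p,
                 max_f_missing = max_f_missing, min_maf = min_maf),
            class = "qc_thresholds")
}

#' Exact one-sided test for heterozygote excess
#'
#' p-value for observing at least the given heterozygote count under the
#' exact conditional Hardy-Weinberg distribution of heterozygote counts given
#' the allele counts (the distribution underlying the classic exact HWE
#' test). Small values flag sites with too many heterozygotes, a common
#' genotyping-artifact signature. Monomorphic sites return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, total
#'   >= 1).
#' @return One-sided p-value `P(het >= observed)`.
#' @examples
#' exc_het_pvalue(5, 0, 5)   # 1: zero hets can never show excess
#' exc_het_pvalue(0, 10, 0)  # all-het site, strongly excess
#' @export
exc_het_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  n_alt <- 2L * n_hom_alt + n_het
  n_minor <- min(n_alt, 2L * n - n_alt)
  if (n_minor == 0L) return(1)
  dist <- exc_het_distribution(n, n_minor)
  sum(dist$prob[dist$het >= n_het])
}

## exact conditional distribution of het counts given n diploids and the
## minor allele count, via the stable up-recurrence
## P(h+2)/P(h) = 4 * nAA(h) * nBB(h) / ((h+1)(h+2))
exc_het_distribution <- function(n, n_minor) {
  n_major <- 2L * n - n_minor
  h <- seq.int(n_minor %% 2L, min(n_minor, n_major), by = 2L)
  w <- numeric(length(h))
  w[1] <- 1
  if (length(h) > 1) {
    for (k in seq_len(length(h) - 1L)) {
      hk <- h[k]
      naa <- (n_minor - hk) / 2
      nbb <- (n_major - hk) / 2
      w[k + 1L] <- w[k] * 4 * naa * nbb / ((hk + 1) * (hk + 2))
      if (w[k + 1L] > 1e280) {      # rescale to avoid overflow at large n
        w <- w / w[k + 1L]
      }
    }
  }
  data.frame(het = h, prob = w / sum(w))
}

#' Per-variant genotype missing rate
#'
#' @param sv an [sv_set].
#' @return Numeric vector: missing genotypes / panel size, per variant.
#' @export
f_missing <- function(sv) {
  rowMeans(is.na(sv$geno))
}

#' Per-variant minor allele frequency
#'
#' Computed from genotypes over non-missing alleles (INFO is never trusted).
#' Variants with every genotype missing return `NA`.
#'
#' @param sv an [sv_set].
#' @return Numeric vector `min(p, 1 - p)` of alt-allele frequency `p`.
#' @export
maf <- function(sv) {
  n_called <- rowSums(!is.na(sv$geno))
  alt <- rowSums(sv$geno, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  pmin(p, 1 - p)
}

#' Apply the four QC filters
#'
#' Filters are applied in the printed order — length, excess-het, missing
#' rate, MAF — and each removed record is attributed to the first filter it
#' fails. Records whose genotypes are all missing have no defined MAF and are
#' counted in their own `all_missing` bucket (reachable only when the missing
#' rate filter is relaxed). The excess-het test pools both groups, since QC
#' precedes the group split.
#'
#' @param sv an [sv_set] of merged records.
#' @param thresholds a [qc_thresholds].
#' @return A list with `sv` (passing records) and `report` (a `qc_report`:
#'   input/output counts and per-filter removal counts that balance).
#' @export
apply_filters <- function(sv, thresholds = qc_thresholds()) {
  stopifnot(inherits(sv, "sv_set"), inherits(thresholds, "qc_thresholds"))
  n <- n_variants(sv)
  het <- rowSums(sv$geno == 1L, na.rm = TRUE)
  hom_alt <- rowSums(sv$geno == 2L, na.rm = TRUE)
  n_called <- rowSums(!is.na(sv$geno))
  hom_ref <- n_called - het - hom_alt
  exchet <- vapply(seq_len(n), function(i) {
    if (n_called[i] == 0) return(1)
    exc_het_pvalue(hom_ref[i], het[i], hom_alt[i])
  }, numeric(1))
  fm <- f_missing(sv)
  mafs <- maf(sv)

  fail <- rep(NA_character_, n)
  fail[is.na(fail) & abs(sv$variants$svlen) > thresholds$max_abs_svlen] <- "length"
  fail[is.na(fail) & exchet < thresholds$min_exchet_p] <- "exc_het"
  fail[is.na(fail) & fm > thresholds$max_f_missing] <- "f_missing"
  fail[is.na(fail) & is.na(mafs)] <- "all_missing"
  fail[is.na(fail) & mafs <= thresholds$min_maf] <- "maf"

  keep <- is.na(fail)
  removed <- vapply(c("length", "exc_het", "f_missing", "maf", "all_missing"),
                    function(f) sum(fail == f, na.rm = TRUE), integer(1))
  report <- structure(list(input_count = n, removed = removed,
                           output_count = sum(keep)),
                      class = "qc_report")
  list(sv = subset_sv(sv, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d in -> %d out\n", x$input_count, x$output_count))
  for (f in names(x$removed)) {
    if (x$removed[[f]] > 0 || f != "all_missing") {
      cat(sprintf("  removed by %-12s %d\n", paste0(f, ":"), x$removed[[f]]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(filter = c("input", names(x$removed), "output"),
             count = c(x$input_count, unname(x$removed), x$output_count),
             stringsAsFactors = FALSE)
}
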