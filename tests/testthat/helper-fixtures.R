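## Fixture builders shared across test files.

make_panel <- function(n_hl = 5, n_ll = 5) {
  sample_panel(
    sprintf("%s%02d", rep(c("HL", "LL"), c(n_hl, n_ll)),
            c(seq_len(n_hl), seq_len(n_ll))),
    rep(c("HL", "LL"), c(n_hl, n_ll))
  )
}

## build an sv_set from a genotype matrix (variants x samples); positions and
## lengths default to well-spaced deletions on one chromosome
make_sv <- function(geno, panel = NULL, pos = NULL, len = 1000,
                    chrom = "chr1", svtype = "DEL", chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(panel)) {
    stopifnot(ncol(geno) %% 2 == 0)
    panel <- make_panel(ncol(geno) / 2, ncol(geno) / 2)
  }
  if (is.null(pos)) pos <- seq(10000, by = 50000, length.out = n)
  len <- rep_len(len, n)
  chrom <- rep_len(chrom, n)
  svtype <- rep_len(svtype, n)
  end <- ifelse(svtype == "INS", pos, pos + len - 1)
  variants <- data.frame(
    id = sprintf("v%03d", seq_len(n)), chrom = chrom,
    pos = as.integer(pos), end = as.integer(end), svtype = svtype,
    svlen = as.integer(ifelse(svtype == "DEL", -len, len)),
    stringsAsFactors = FALSE
  )
  sv_set(variants, geno, panel, chrom_lengths = chrom_lengths)
}

## genotype row from per-group counts c(n_hom_ref, n_het, n_hom_alt)
geno_row <- function(hl_counts, ll_counts, n_hl = sum(hl_counts),
                     n_ll = sum(ll_counts)) {
  c(rep(c(0L, 1L, 2L), hl_counts), rep(NA_integer_, n_hl - sum(hl_counts)),
    rep(c(0L, 1L, 2L), ll_counts), rep(NA_integer_, n_ll - sum(ll_counts)))
}

## small coding-gene annotation: one gene [start, end] on `strand` with
## exon/CDS/UTR structure mirroring simulate_annotation's layout
toy_gene <- function(gene_id, chrom, start, L, strand = "+") {
  rel <- function(a, b) c(start + round(a * L), start + round(b * L) - 1)
  ex1 <- rel(0, 0.10); ex2 <- rel(0.45, 0.55); ex3 <- rel(0.90, 1)
  utr_lo <- rel(0, 0.04); utr_hi <- rel(0.96, 1)
  utr5 <- if (strand == "+") utr_lo else utr_hi
  utr3 <- if (strand == "+") utr_hi else utr_lo
  end <- start + L - 1
  data.frame(
    chrom = chrom,
    start = c(start, ex1[1], ex2[1], ex3[1], utr_lo[2] + 1, ex2[1], ex3[1],
              utr5[1], utr3[1]),
    end = c(end, ex1[2], ex2[2], ex3[2], ex1[2], ex2[2], utr_hi[1] - 1,
            utr5[2], utr3[2]),
    strand = strand, gene_id = gene_id,
    feature_kind = c("gene", "exon", "exon", "exon", "CDS", "CDS", "CDS",
                     "five_prime_UTR", "three_prime_UTR"),
    stringsAsFactors = FALSE
  )
}

qc_toy_sv <- function() {
  panel <- read_sample_panel(system.file("extdata", "qc_toy_panel.tsv",
                                         package = "cnvselscan"))
  read_sv_vcf(system.file("extdata", "qc_toy.vcf", package = "cnvselscan"),
              panel)
}

## genome-wide ratio-of-sums FST over all usable sites
genomewide_fst <- function(sv) {
  comp <- cnvselscan:::site_components(sv)
  sum(comp[, "a"], na.rm = TRUE) / sum(rowSums(comp), na.rm = TRUE)
}
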