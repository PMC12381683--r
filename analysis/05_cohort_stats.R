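#!/usr/bin/env Rscript

## Stage 5 — cohort distribution statistics and population structure.
##
## Per-group allele-frequency spectra with per-bin Fisher exact tests,
## per-chromosome presence chi-square tests with Bonferroni correction, and
## GRM-based PCA of the cohort.

suppressMessages(library(cnvselscan))

panel <- read_sample_panel("results/data/panel.tsv")
qc <- read_sv_vcf("results/data/qc.vcf", panel)

freqs <- group_frequencies(qc)
spectrum <- frequency_spectrum(freqs)
print(spectrum)
fisher <- bin_fisher_tests(spectrum)
sig <- fisher[fisher$p < 0.05, ]
message(sprintf("frequency bins with Fisher p < 0.05: %d%s", nrow(sig),
                if (nrow(sig)) paste0(" (",
                  paste(sprintf("[%.1f,%.1f)", sig$bin_start, sig$bin_end),
                        collapse = ", "), ")") else ""))

chrom_tests <- chrom_distribution_tests(qc)
message(sprintf("chromosome distribution: %d of %d tests significant after Bonferroni",
                sum(chrom_tests$significant, na.rm = TRUE), nrow(chrom_tests)))

pca <- grm_pca(qc)
message(sprintf("PCA: PC1 explains %.1f%%, PC2 %.1f%% of GRM variance",
                100 * pca$varexp[1], 100 * pca$varexp[2]))
hl <- pca$scores$PC1[pca$scores$group == "HL"]
ll <- pca$scores$PC1[pca$scores$group == "LL"]
message(sprintf("PC1 separates the groups: %s",
                max(hl) < min(ll) || max(ll) < min(hl)))

write.table(freqs, "results/group_frequencies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(fisher, "results/bin_fisher.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(chrom_tests, "results/chrom_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pca$scores, "results/pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
dir.create("results/figures", showWarnings = FALSE)
grDevices::png("results/figures/pca.png", 700, 600, res = 110)
plot_pca(pca)
grDevices::dev.off()
message("wrote results/{group_frequencies,bin_fisher,chrom_tests,pca}.tsv and figures/pca.png")
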