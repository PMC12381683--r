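#!/usr/bin/env Rscript

## Stage 2 — population merging and quality control.
##
## Collapses the per-sample callsets into population variants (50% reciprocal
## overlap for deletions, genotype concordance >= 0.95) and applies the four
## QC filters: |SVLEN| <= 10 Mb, excess-het p >= 0.05, F_MISSING <= 0.2,
## MAF > 0. Reports how well merging reconstructs the known truth set.

suppressMessages(library(cnvselscan))

panel <- read_sample_panel("results/data/panel.tsv")
callsets <- read_sv_vcf("results/data/callsets.vcf", panel)
truth <- read_sv_vcf("results/data/truth.vcf", panel)

merged <- merge_population(callsets)
message(sprintf("merged %d records into %d variants (truth carries %d)",
                n_variants(callsets), n_variants(merged$sv), n_variants(truth)))
supp <- merged$sv$variants$support
message(sprintf("cluster support: median %d, range %d-%d",
                median(supp), min(supp), max(supp)))

qc <- apply_filters(merged$sv)
print(qc$report)

write_sv_vcf(qc$sv, "results/data/qc.vcf")
write.table(merged$clusters, "results/merge_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(qc$report), "results/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/data/qc.vcf, results/merge_report.tsv, results/qc_report.tsv")
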