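#!/usr/bin/env Rscript

## Stage 4 — candidate filtering and feature annotation.
##
## Drops candidate loci that overlap no gene body or whose best
## supporting-window FST is negative, then classifies every QC-passed CNV
## into genomic feature categories (exonic ... intergenic) for the cohort
## overview.

suppressMessages(library(cnvselscan))

panel <- read_sample_panel("results/data/panel.tsv")
qc <- read_sv_vcf("results/data/qc.vcf", panel)
genes <- read_gene_annotation("results/data/genes.gff3")
loci <- read.table("results/loci_raw.tsv", header = TRUE,
                   colClasses = c(id = "character", chrom = "character"))

candidates <- filter_candidates(loci, genes)
message(sprintf("candidate loci: %d of %d survive the gene/FST exclusions",
                nrow(candidates), nrow(loci)))
gene_ids <- unique(unlist(strsplit(candidates$genes, ",")))
message(sprintf("candidate genes: %d (%s%s)", length(gene_ids),
                paste(head(gene_ids, 5), collapse = ", "),
                if (length(gene_ids) > 5) ", ..." else ""))

truth <- read.table("results/data/truth_table.tsv", header = TRUE)
## merged representatives carry ids of the form <truth_id>_<sample>
in_sweep <- sub("_.*$", "", candidates$id) %in% truth$id[truth$in_sweep]
message(sprintf("%d of %d candidates lie in the planted sweep region",
                sum(in_sweep), nrow(candidates)))

calls <- classify_features(qc, genes)
fs <- feature_summary(calls)
print(fs[fs$count > 0, ])

write.table(candidates, "results/candidate_loci.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(calls, "results/feature_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(fs, "results/feature_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/candidate_loci.tsv, results/feature_calls.tsv, results/feature_summary.tsv")
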