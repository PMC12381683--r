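#!/usr/bin/env Rscript

## Stage 1 — simulate the study cohort.
##
## Builds a synthetic analogue of a 15 + 15 trait-divergent goat cohort:
## deletion CNVs on a 2-chromosome 80 Mb genome with modest background
## differentiation (F = 0.03) and one 200 kb region where the deletion has
## nearly swept to fixation in the HL group while staying intermediate in LL
## — the signature the downstream scan is meant to find. Also emits the
## per-sample "caller" callsets (jittered, with dropout) that stage 2 merges,
## plus a toy gene annotation.

suppressMessages(library(cnvselscan))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_hl = 15, n_ll = 15, n_variants = 6000,
  chrom_lengths = c(chr1 = 5e7, chr2 = 3e7),
  target_fst = 0.03, missing_rate = 0.05,
  len_range = c(1e3, 5e3),
  sweep = sweep_spec("chr1", 2.5e7, 2.53e7, hl_freq = 0.98, ll_freq = 0.5),
  seed = 2024
)
sim <- simulate_genotype_matrix(cfg)
message(sprintf("simulated %d deletion CNVs for %d samples (%d in sweep region)",
                n_variants(sim$sv), nrow(sim$sv$panel), sum(sim$truth$in_sweep)))

callsets <- fragment_to_callsets(sim$sv, jitter_bp = 150, dropout = 0.05,
                                 seed = 2025)
message(sprintf("fragmented into %d per-sample records (mean %.1f per variant)",
                n_variants(callsets),
                n_variants(callsets) / n_variants(sim$sv)))

ann <- simulate_annotation(cfg$chrom_lengths, n_genes = 1200,
                           gene_length = 20000, seed = 2026)
message(sprintf("annotation: %d genes covering %.1f%% of the genome",
                nrow(gene_bodies(ann)),
                100 * sum(with(gene_bodies(ann), end - start + 1)) /
                  sum(cfg$chrom_lengths)))

write_sv_vcf(sim$sv, "results/data/truth.vcf")
write_sv_vcf(callsets, "results/data/callsets.vcf")
write_sample_panel(sim$sv$panel, "results/data/panel.tsv")
write_gene_annotation(ann, "results/data/genes.gff3")
write.table(sim$truth, "results/data/truth_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/data/{truth.vcf,callsets.vcf,panel.tsv,genes.gff3,truth_table.tsv}")
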