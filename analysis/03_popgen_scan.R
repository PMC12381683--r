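#!/usr/bin/env Rscript

## Stage 3 — windowed selection statistics and the dual-criterion scan.
##
## Computes Weir-Cockerham FST and per-group nucleotide diversity in 100 kb
## windows sliding by 10 kb, contrasts the groups by log2(piHL/piLL), and
## selects windows in the top 1% of FST that also sit in the lower 1% tail of
## the diversity ratio (the analysis targets diversity loss in the HL group,
## where the sweep was planted).

suppressMessages(library(cnvselscan))

panel <- read_sample_panel("results/data/panel.tsv")
qc <- read_sv_vcf("results/data/qc.vcf", panel)
grid <- window_grid(1e5, 1e4, attr(qc, "chrom_lengths"))

stats <- window_stats(qc, grid)
message(sprintf("%d windows, %d with FST defined, %d with a defined log2 ratio",
                nrow(stats), sum(is.finite(stats$fst)),
                sum(is.finite(stats$log2_ratio))))

scan <- select_candidate_windows(stats, scan_config(0.01, ratio_tail = "lower"))
message(sprintf("top-1%% FST windows: %d; lower-1%% ratio windows: %d; intersection: %d",
                nrow(scan$fst_top), nrow(scan$ratio_top), nrow(scan$selected)))

truth <- read.table("results/data/truth_table.tsv", header = TRUE)
sweep_range <- range(truth$pos[truth$in_sweep])
inside <- stats$start >= sweep_range[1] & stats$end <= sweep_range[2] &
  stats$chrom == truth$chrom[truth$in_sweep][1]
sel_key <- paste(scan$selected$chrom, scan$selected$start)
message(sprintf("sweep-region windows recovered by the intersection: %d of %d",
                sum(paste(stats$chrom, stats$start)[inside] %in% sel_key),
                sum(inside)))

loci <- windows_to_loci(scan$selected, qc)
message(sprintf("candidate loci before gene/FST filtering: %d", nrow(loci)))

write.table(stats, "results/windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(site_stats(qc), "results/sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(scan$selected, "results/selected_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(loci, "results/loci_raw.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

dir.create("results/figures", showWarnings = FALSE)
grDevices::png("results/figures/manhattan_fst.png", 1400, 500, res = 110)
plot_manhattan(stats, "fst", highlight = scan$selected,
               main = "windowed Weir-Cockerham FST")
grDevices::dev.off()
grDevices::png("results/figures/manhattan_ratio.png", 1400, 500, res = 110)
plot_manhattan(stats, "log2_ratio", highlight = scan$selected,
               main = "log2(piHL/piLL)")
grDevices::dev.off()
for (track in c("pi_hl", "pi_ll")) {
  grDevices::png(sprintf("results/figures/manhattan_%s.png", track),
                 1400, 500, res = 110)
  plot_manhattan(stats, track, highlight = scan$selected,
                 main = sprintf("windowed %s", track))
  grDevices::dev.off()
}
message("wrote results/windows.tsv, results/selected_windows.tsv, results/loci_raw.tsv and figures")
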