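#' End-to-end pipeline configuration
#'
#' Bundles all stage parameters with the input paths. Defaults reproduce the
#' analysis settings used throughout: 50%/90% merge overlap with 0.95
#' genotype consistency, the four QC filters at their printed bounds,
#' 100 kb / 10 kb windows and a top-1% dual-criterion scan.
#'
#' @param vcf multi-sample SV VCF path.
#' @param panel sample-panel path (see [read_sample_panel]).
#' @param annotation GFF3 or BED gene-annotation path.
#' @param out_dir output directory (created if needed).
#' @param merge a [merge_thresholds].
#' @param qc a [qc_thresholds].
#' @param window_size,step window grid parameters in bp.
#' @param scan a [scan_config].
#' @param flank_bp flank width for feature classification.
#' @param alpha significance level for distribution tests.
#' @param n_components PCA components.
#' @export
pipeline_config <- function(vcf, panel, annotation, out_dir,
                            merge = merge_thresholds(),
                            qc = qc_thresholds(),
                            window_size = 1e5, step = 1e4,
                            scan = scan_config(),
                            flank_bp = 1000, alpha = 0.05,
                            n_components = 2) {
  for (p in c(vcf, panel, annotation)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  structure(list(vcf = vcf, panel = panel, annotation = annotation,
                 out_dir = out_dir, merge = merge, qc = qc,
                 window_size = window_size, step = step, scan = scan,
                 flank_bp = flank_bp, alpha = alpha,
                 n_components = n_components),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full CNV selection-signature pipeline
#'
#' Stage order: read -> merge -> QC -> window statistics -> dual-criterion
#' scan -> candidate loci + gene filtering -> feature annotation -> cohort
#' statistics -> PCA. Every intermediate table is written to `out_dir`
#' together with a JSON manifest recording parameters, input checksums and
#' per-stage record counts. Re-running with identical inputs and config
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with every stage result plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  panel <- read_sample_panel(config$panel)
  sv_raw <- read_sv_vcf(config$vcf, panel)
  genes <- read_gene_annotation(config$annotation)

  merged <- merge_population(sv_raw, config$merge)
  write_sv_vcf(merged$sv, out("merged.vcf"))
  write_tsv(merged$clusters, out("merge_report.tsv"))

  qc <- apply_filters(merged$sv, config$qc)
  write_sv_vcf(qc$sv, out("qc.vcf"))
  write_tsv(as.data.frame(qc$report), out("qc_report.tsv"))

  chrom_lengths <- attr(qc$sv, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(qc$sv$variants$end, qc$sv$variants$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  grid <- window_grid(config$window_size, config$step, chrom_lengths)
  stats <- window_stats(qc$sv, grid)
  write_tsv(stats, out("windows.tsv"))
  write_tsv(site_stats(qc$sv), out("sites.tsv"))

  scan <- select_candidate_windows(stats, config$scan)
  write_tsv(scan$selected, out("selected_windows.tsv"))

  loci <- windows_to_loci(scan$selected, qc$sv)
  candidates <- filter_candidates(loci, genes)
  write_tsv(candidates, out("candidate_loci.tsv"))

  calls <- classify_features(qc$sv, genes, config$flank_bp)
  write_tsv(calls, out("feature_calls.tsv"))
  write_tsv(feature_summary(calls), out("feature_summary.tsv"))

  freqs <- group_frequencies(qc$sv)
  write_tsv(freqs, out("group_frequencies.tsv"))
  spectrum <- frequency_spectrum(freqs)
  write_tsv(data.frame(bin_start = spectrum$bin_start,
                       bin_end = spectrum$bin_end,
                       counts_hl = spectrum$counts_hl,
                       counts_ll = spectrum$counts_ll),
            out("spectrum.tsv"))
  chrom_tests <- chrom_distribution_tests(qc$sv, config$alpha)
  write_tsv(chrom_tests, out("chrom_tests.tsv"))
  fisher <- bin_fisher_tests(spectrum)
  write_tsv(fisher, out("bin_fisher.tsv"))

  pca <- grm_pca(qc$sv, config$n_components)
  write_tsv(pca$scores, out("pca.tsv"))

  manifest <- list(
    package = "cnvselscan",
    version = as.character(utils::packageVersion("cnvselscan")),
    parameters = list(
      merge = unclass(config$merge), qc = unclass(config$qc),
      window_size = config$window_size, step = config$step,
      scan = unclass(config$scan), flank_bp = config$flank_bp,
      alpha = config$alpha
    ),
    inputs = as.list(tools::md5sum(c(vcf = config$vcf, panel = config$panel,
                                     annotation = config$annotation))),
    counts = list(
      input_records = n_variants(sv_raw),
      merged = n_variants(merged$sv),
      qc_passed = n_variants(qc$sv),
      windows = nrow(stats),
      ranked_fst = sum(is.finite(stats$fst)),
      ranked_ratio = sum(is.finite(stats$log2_ratio)),
      fst_top = nrow(scan$fst_top),
      ratio_top = nrow(scan$ratio_top),
      selected_windows = nrow(scan$selected),
      candidate_loci_raw = nrow(loci),
      candidate_loci = nrow(candidates),
      candidate_genes = length(unique(unlist(
        strsplit(candidates$genes, ",", fixed = TRUE))))
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sv_raw = sv_raw, merged = merged, qc = qc, grid = grid,
                 window_stats = stats, scan = scan, loci = loci,
                 candidates = candidates, feature_calls = calls,
                 spectrum = spectrum, chrom_tests = chrom_tests,
                 bin_fisher = fisher, pca = pca, manifest = manifest))
}
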