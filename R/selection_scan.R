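#' Scan configuration for the dual-criterion outlier selection
#'
#' Candidate windows are those lying simultaneously in the top tail of the
#' windowed FST distribution and in the extreme tail(s) of the log2
#' diversity-ratio distribution, each at the empirical `quantile` (default
#' top 1%). The FST tail is always upper; the ratio tail defaults to `both`
#' (the quantile split half-and-half between tails, since a sweep in HL
#' depresses the ratio and a sweep in LL raises it) and can be fixed to one
#' side when the direction of selection is known.
#'
#' @param quantile tail mass in `(0, 0.5)` (default 0.01).
#' @param ratio_tail `"both"`, `"lower"` or `"upper"`.
#' @export
scan_config <- function(quantile = 0.01, ratio_tail = c("both", "lower", "upper")) {
  if (quantile <= 0 || quantile >= 0.5) stop("quantile must be in (0, 0.5)")
  structure(list(quantile = quantile, ratio_tail = match.arg(ratio_tail)),
            class = "scan_config")
}

#' Top-quantile windows of one statistic
#'
#' Ranks the windows whose statistic is defined (finite) and returns those at
#' or beyond the empirical quantile threshold; ties at the threshold are all
#' included, so the selected fraction is at least `quantile`.
#'
#' @param stats window table ([window_stats]).
#' @param statistic column name to rank (e.g. `"fst"`, `"log2_ratio"`).
#' @param quantile tail mass.
#' @param tail `"upper"`, `"lower"`, or `"both"` (half the mass per side).
#' @return The selected window rows (with all statistic columns).
#' @export
top_quantile_windows <- function(stats, statistic, quantile = 0.01,
                                 tail = c("upper", "lower", "both")) {
  tail <- match.arg(tail)
  v <- stats[[statistic]]
  if (is.null(v)) stop("no column '", statistic, "' in window table")
  defined <- is.finite(v)
  ranked <- stats[defined, , drop = FALSE]
  x <- v[defined]
  if (nrow(ranked) == 0) return(ranked)
  if (length(unique(x)) == 1L) {
    warning("all '", statistic, "' values identical; empty selection", call. = FALSE)
    return(ranked[0, , drop = FALSE])
  }
  if (nrow(ranked) < 1 / quantile) {
    warning("fewer than 1/quantile ranked windows; tail is coarse", call. = FALSE)
  }
  pick <- switch(tail,
    upper = x >= stats::quantile(x, 1 - quantile, names = FALSE),
    lower = x <= stats::quantile(x, quantile, names = FALSE),
    both = x >= stats::quantile(x, 1 - quantile / 2, names = FALSE) |
           x <= stats::quantile(x, quantile / 2, names = FALSE)
  )
  ranked[pick, , drop = FALSE]
}

#' Intersection of two selected-window sets
#'
#' Windows (keyed by chromosome, start, end) present in both sets — the
#' dual-criterion rule requiring a window to rank in the top tail of FST and
#' of the diversity-ratio scan simultaneously.
#'
#' @param fst_top,ratio_top window tables from [top_quantile_windows] over
#'   the same grid.
#' @return The window rows of `fst_top` also present in `ratio_top`.
#' @export
intersect_candidates <- function(fst_top, ratio_top) {
  key <- function(w) paste(w$chrom, w$start, w$end)
  fst_top[key(fst_top) %in% key(ratio_top), , drop = FALSE]
}

#' Run the dual-criterion window scan
#'
#' @param stats window table from [window_stats].
#' @param config a [scan_config].
#' @return List with `fst_top`, `ratio_top` and `selected` (their
#'   intersection).
#' @export
select_candidate_windows <- function(stats, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  fst_top <- top_quantile_windows(stats, "fst", config$quantile, "upper")
  ratio_top <- top_quantile_windows(stats, "log2_ratio", config$quantile,
                                    config$ratio_tail)
  list(fst_top = fst_top, ratio_top = ratio_top,
       selected = intersect_candidates(fst_top, ratio_top))
}

#' Map selected windows to candidate CNV loci
#'
#' Every record whose start position falls inside at least one selected
#' window becomes one candidate locus (deduplicated across the overlapping
#' windows of the sliding grid), carrying the count of supporting windows
#' and the maximum supporting-window FST.
#'
#' @param windows selected window rows.
#' @param sv the QC-passed [sv_set] used for the scan.
#' @return `data.frame` of loci: `id`, `chrom`, `pos`, `end`, `svtype`,
#'   `n_windows`, `max_window_fst`.
#' @export
windows_to_loci <- function(windows, sv) {
  v <- sv$variants
  if (nrow(windows) == 0 || nrow(v) == 0) {
    return(data.frame(id = character(0), chrom = character(0), pos = integer(0),
                      end = integer(0), svtype = character(0),
                      n_windows = integer(0), max_window_fst = numeric(0),
                      stringsAsFactors = FALSE))
  }
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start, windows$end))
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hits <- GenomicRanges::findOverlaps(vgr, wgr)
  if (length(hits) == 0) {
    return(windows_to_loci(windows[0, ], sv))
  }
  qi <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  loci <- lapply(split(wi, qi), function(ws) {
    c(n_windows = length(ws), max_window_fst = max(windows$fst[ws]))
  })
  sel <- as.integer(names(loci))
  out <- data.frame(
    id = v$id[sel], chrom = v$chrom[sel], pos = v$pos[sel], end = v$end[sel],
    svtype = v$svtype[sel],
    n_windows = vapply(loci, `[[`, numeric(1), "n_windows"),
    max_window_fst = vapply(loci, `[[`, numeric(1), "max_window_fst"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$id), , drop = FALSE]
}

#' Final candidate filtering
#'
#' Applies the two exclusion rules to candidate loci: loci overlapping no
#' gene body, and loci whose best supporting-window FST is negative, are
#' removed (zero is not negative, so FST = 0 loci are retained).
#'
#' @param loci candidate table from [windows_to_loci].
#' @param genes a [gene_annotation].
#' @return The retained loci with a `genes` column (comma-separated
#'   overlapping gene ids).
#' @export
filter_candidates <- function(loci, genes) {
  gene_lists <- assign_genes(loci, genes)
  loci$genes <- vapply(gene_lists, paste, character(1), collapse = ",")
  keep <- lengths(gene_lists) > 0 & loci$max_window_fst >= 0
  loci[keep, , drop = FALSE]
}
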