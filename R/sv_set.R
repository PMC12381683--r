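#' Sample panel: sample-to-group assignment
#'
#' A sample panel maps every sample of the cohort to one of the two contrast
#' groups, `HL` (high litter size) and `LL` (low litter size). Sample order in
#' the panel is the canonical sample order for all genotype matrices.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character vector of the same length with values `"HL"` or
#'   `"LL"`; each group must be non-empty.
#' @return A `data.frame` of class `sample_panel` with columns `sample_id`
#'   and `group`.
#' @examples
#' sample_panel(c("a", "b", "c", "d"), c("HL", "HL", "LL", "LL"))
#' @export
sample_panel <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group)) stop("sample_id and group lengths differ")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in panel")
  if (!all(group %in% c("HL", "LL"))) stop("panel groups must be 'HL' or 'LL'")
  if (!all(c("HL", "LL") %in% group)) stop("both groups HL and LL must be non-empty")
  structure(
    data.frame(sample_id = sample_id, group = group, stringsAsFactors = FALSE),
    class = c("sample_panel", "data.frame")
  )
}

#' @rdname sample_panel
#' @param panel a `sample_panel`.
#' @param which group label, `"HL"` or `"LL"`.
#' @export
panel_samples <- function(panel, which) panel$sample_id[panel$group == which]

#' Read / write a sample panel
#'
#' The on-disk format is a headerless two-column whitespace-delimited table
#' (`sample_id`, `group`); gzip-compressed files are accepted.
#'
#' @param path file path.
#' @return `read_sample_panel` returns a [sample_panel]; `write_sample_panel`
#'   returns `path` invisibly.
#' @export
read_sample_panel <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample_id", "group"))
  sample_panel(tab$sample_id, tab$group)
}

#' @rdname read_sample_panel
#' @param panel a `sample_panel`.
#' @export
write_sample_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an SV genotype set
#'
#' The central in-memory container: a variant table plus a variant-by-sample
#' genotype dosage matrix. Genotypes are coded as the count of the alternate
#' (deletion) allele: 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing.
#'
#' @param variants `data.frame` with columns `id`, `chrom`, `pos`, `end`,
#'   `svtype` (one of DEL, INS, INV, DUP) and `svlen` (signed; negative for
#'   deletions). Coordinates are 1-based inclusive; for deletions
#'   `end = pos + |svlen| - 1`.
#' @param geno integer matrix, `nrow(variants)` rows, one column per panel
#'   sample, values in `{0, 1, 2, NA}`.
#' @param panel a [sample_panel]; column order of `geno` must match.
#' @param chrom_lengths optional named vector of chromosome lengths, kept as
#'   an attribute and used for VCF contig headers and window grids.
#' @return An object of class `sv_set`.
#' @export
sv_set <- function(variants, geno, panel, chrom_lengths = NULL) {
  required <- c("id", "chrom", "pos", "end", "svtype", "svlen")
  if (!all(required %in% names(variants))) {
    stop("variants must have columns: ", paste(required, collapse = ", "))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants)) stop("geno rows must match variants rows")
  if (ncol(geno) != nrow(panel)) stop("geno columns must match panel size")
  if (!all(is.na(geno) | (geno >= 0L & geno <= 2L))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  if (!all(variants$svtype %in% c("DEL", "INS", "INV", "DUP"))) {
    stop("svtype must be one of DEL, INS, INV, DUP")
  }
  span <- variants$svtype != "INS"
  if (any(variants$pos[span] > variants$end[span])) stop("pos > end for a spanning variant")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  colnames(geno) <- panel$sample_id
  rownames(geno) <- variants$id
  structure(
    list(variants = variants, geno = geno, panel = panel),
    chrom_lengths = chrom_lengths,
    class = "sv_set"
  )
}

#' @export
print.sv_set <- function(x, ...) {
  cat(sprintf("<sv_set> %d variants x %d samples (%d HL / %d LL)\n",
              nrow(x$variants), nrow(x$panel),
              sum(x$panel$group == "HL"), sum(x$panel$group == "LL")))
  cat("  types:", paste(sprintf("%s=%d", names(table(x$variants$svtype)),
                                table(x$variants$svtype)), collapse = " "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of variants in an sv_set
#' @param sv an `sv_set`.
#' @export
n_variants <- function(sv) nrow(sv$variants)

## genotype submatrix of one group, variants x samples
group_geno <- function(sv, which) {
  sv$geno[, sv$panel$group == which, drop = FALSE]
}

## subset variants by logical/integer index, keeping attributes
subset_sv <- function(sv, idx) {
  out <- sv_set(sv$variants[idx, , drop = FALSE],
                sv$geno[idx, , drop = FALSE],
                sv$panel,
                chrom_lengths = attr(sv, "chrom_lengths"))
  out
}
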