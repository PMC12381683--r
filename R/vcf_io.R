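## SV-VCF dialect: VCF 4.2, symbolic ALT (<DEL>, <INS>, <INV>, <DUP>),
## INFO keys SVTYPE / SVLEN (negative for deletions) / END, GT-only FORMAT.

gt_to_dosage <- function(gt) {
  ## take the GT subfield, ignore phasing; any half-missing call is MISSING
  gt <- sub(":.*$", "", gt)
  gt <- gsub("\\|", "/", gt)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0")] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% c("1/1", "1")] <- 2L
  out
}

dosage_to_gt <- function(d) {
  gt <- rep("./.", length(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  gt
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Read a multi-sample SV VCF
#'
#' Accepts the symbolic-ALT structural-variant dialect (SVTYPE/SVLEN/END in
#' INFO, GT in FORMAT); gzip-compressed files are handled. Lines that are
#' multiallelic or carry no SVTYPE are skipped with a warning carrying the
#' skip count. A missing END for a deletion is reconstructed as
#' `POS + |SVLEN| - 1`; when END and SVLEN disagree by more than 1 bp, END
#' wins and a warning is raised. Sample columns are reordered to panel order.
#'
#' @param path VCF path.
#' @param panel a [sample_panel]; every panel sample must be present in the
#'   VCF (extra VCF samples are dropped).
#' @return An [sv_set].
#' @export
read_sv_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  if (is.null(fix) || nrow(fix) == 0) stop("no records in ", path)
  samples <- colnames(gt)[-1]
  if (!all(panel$sample_id %in% samples)) {
    stop("panel samples absent from VCF: ",
         paste(setdiff(panel$sample_id, samples), collapse = ", "))
  }
  info <- fix[, "INFO"]
  svtype <- info_field(info, "SVTYPE")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  keep <- !is.na(svtype) & !multi & svtype %in% c("DEL", "INS", "INV", "DUP")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    warning(n_skip, " non-SV or multiallelic line(s) skipped", call. = FALSE)
  }
  if (!any(keep)) stop("no usable SV records in ", path)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  svtype <- svtype[keep]
  pos <- as.integer(fix[, "POS"])
  svlen <- suppressWarnings(as.integer(info_field(fix[, "INFO"], "SVLEN")))
  end <- suppressWarnings(as.integer(info_field(fix[, "INFO"], "END")))
  need_end <- is.na(end)
  end[need_end] <- ifelse(svtype[need_end] == "INS", pos[need_end],
                          pos[need_end] + abs(svlen[need_end]) - 1L)
  inconsistent <- svtype == "DEL" & !is.na(svlen) & !need_end &
    abs((end - pos + 1L) - abs(svlen)) > 1L
  if (any(inconsistent)) {
    warning(sum(inconsistent), " record(s) with END/SVLEN disagreement > 1 bp; END kept",
            call. = FALSE)
  }
  svlen[is.na(svlen)] <- ifelse(svtype[is.na(svlen)] == "DEL", -1L, 1L) *
    (end[is.na(svlen)] - pos[is.na(svlen)] + 1L)
  id <- fix[, "ID"]
  blank <- is.na(id) | id == "."
  id[blank] <- sprintf("sv_%s_%d", fix[blank, "CHROM"], pos[blank])
  geno <- apply(gt[, panel$sample_id, drop = FALSE], 2, gt_to_dosage)
  geno <- matrix(as.integer(geno), nrow = nrow(fix),
                 dimnames = list(NULL, panel$sample_id))
  variants <- data.frame(
    id = id, chrom = fix[, "CHROM"], pos = pos, end = end,
    svtype = svtype, svlen = svlen, stringsAsFactors = FALSE
  )
  chrom_lengths <- vcf_contig_lengths(vcf@meta)
  sv_set(variants, geno, panel, chrom_lengths = chrom_lengths)
}

vcf_contig_lengths <- function(meta) {
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig) == 0) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
  if (any(is.na(lens))) return(NULL)
  setNames(lens, ids)
}

#' Write an sv_set as a multi-sample SV VCF
#'
#' @param sv an [sv_set]. Contig header lines are emitted when the set
#'   carries chromosome lengths.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(sv, path) {
  v <- sv$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cnvselscan",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant (negative for deletions)">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=INS,Description="Insertion">',
    '##ALT=<ID=INV,Description="Inversion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  cl <- attr(sv, "chrom_lengths")
  if (!is.null(cl)) {
    header <- append(header,
                     sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
                     after = 2L)
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", sv$panel$sample_id),
                            collapse = "\t"))
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", v$svtype, v$svlen, v$end)
  gt <- matrix(dosage_to_gt(sv$geno), nrow = nrow(v))
  body <- paste(v$chrom, v$pos, v$id, "N", paste0("<", v$svtype, ">"),
                ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  if (nrow(v) == 0) body <- character(0)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
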