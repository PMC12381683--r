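#' Gene annotation container and readers
#'
#' Gene annotations are held as a plain data.frame of 1-based inclusive
#' intervals with columns `chrom`, `start`, `end`, `strand`, `gene_id` and
#' `feature_kind` (one of `gene`, `exon`, `CDS`, `five_prime_UTR`,
#' `three_prime_UTR`, `ncRNA_gene`, `ncRNA_exon`). Sub-features must lie
#' within their gene body. GFF3 files are read natively; BED intervals
#' (0-based half-open) are converted on read and each BED line becomes one
#' gene body.
#'
#' @param df data.frame with the columns above.
#' @return A `gene_annotation` data.frame.
#' @export
gene_annotation <- function(df) {
  required <- c("chrom", "start", "end", "strand", "gene_id", "feature_kind")
  if (!all(required %in% names(df))) {
    stop("annotation must have columns: ", paste(required, collapse = ", "))
  }
  kinds <- c("gene", "exon", "CDS", "five_prime_UTR", "three_prime_UTR",
             "ncRNA_gene", "ncRNA_exon")
  if (!all(df$feature_kind %in% kinds)) {
    stop("unknown feature_kind: ",
         paste(setdiff(unique(df$feature_kind), kinds), collapse = ", "))
  }
  if (any(df$start > df$end)) stop("feature start > end")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  ## sub-features must lie inside their gene body
  bodies <- df[df$feature_kind %in% c("gene", "ncRNA_gene"), ]
  subs <- df[!df$feature_kind %in% c("gene", "ncRNA_gene"), ]
  if (nrow(subs) > 0) {
    m <- match(subs$gene_id, bodies$gene_id)
    bad <- is.na(m) | subs$start < bodies$start[m] | subs$end > bodies$end[m]
    if (any(bad)) stop("sub-features outside their gene body: ",
                       paste(unique(subs$gene_id[bad]), collapse = ", "))
  }
  structure(df, class = c("gene_annotation", "data.frame"))
}

#' @rdname gene_annotation
#' @param ann a `gene_annotation`.
#' @return `gene_bodies` returns only the `gene`/`ncRNA_gene` rows.
#' @export
gene_bodies <- function(ann) {
  ann[ann$feature_kind %in% c("gene", "ncRNA_gene"), , drop = FALSE]
}

## GFF3 type -> internal feature_kind vocabulary
.gff_kind_map <- c(
  gene = "gene", mRNA = NA, transcript = NA,
  exon = "exon", CDS = "CDS",
  five_prime_UTR = "five_prime_UTR", three_prime_UTR = "three_prime_UTR",
  ncRNA_gene = "ncRNA_gene", lnc_RNA = NA, ncRNA = NA, ncRNA_exon = "ncRNA_exon"
)

#' Read a gene annotation from GFF3 or BED
#'
#' @param path file path (gzip accepted). Format is inferred from the
#'   extension unless given explicitly.
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @return A [gene_annotation].
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.bed$", base, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0) {
      return(gene_annotation(data.frame(chrom = character(0), start = integer(0),
                                        end = integer(0), strand = character(0),
                                        gene_id = character(0),
                                        feature_kind = character(0))))
    }
    name <- gr$name %||% sprintf("gene%03d", seq_along(gr))
    name[is.na(name)] <- sprintf("gene%03d", which(is.na(name)))
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    return(gene_annotation(data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
      strand = strand, gene_id = name, feature_kind = "gene",
      stringsAsFactors = FALSE
    )))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(gene_annotation(data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), strand = character(0),
                                      gene_id = character(0),
                                      feature_kind = character(0))))
  }
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  ## resolve each feature to its owning gene id (through one transcript level)
  is_gene <- type %in% c("gene", "ncRNA_gene")
  owner <- setNames(id[is_gene], id[is_gene])
  gene_of <- function(p) {
    while (!is.na(p) && !p %in% names(owner)) {
      i <- match(p, id)
      if (is.na(i)) return(NA_character_)
      p <- parent[i]
    }
    p
  }
  gid <- ifelse(is_gene, id, vapply(parent, gene_of, character(1)))
  kind <- unname(.gff_kind_map[type])
  ## ncRNA exons: exon whose owning gene is an ncRNA_gene
  nc_genes <- id[type == "ncRNA_gene"]
  kind[type == "exon" & gid %in% nc_genes] <- "ncRNA_exon"
  keep <- !is.na(kind) & !is.na(gid)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  ann <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr))[keep],
    start = BiocGenerics::start(gr)[keep], end = BiocGenerics::end(gr)[keep],
    strand = strand[keep], gene_id = gid[keep], feature_kind = kind[keep],
    stringsAsFactors = FALSE
  )
  rownames(ann) <- NULL
  gene_annotation(ann)
}

#' Write a gene annotation to GFF3
#'
#' @param ann a [gene_annotation].
#' @param path output path.
#' @export
write_gene_annotation <- function(ann, path) {
  is_gene <- ann$feature_kind %in% c("gene", "ncRNA_gene")
  type <- ann$feature_kind
  type[type == "ncRNA_exon"] <- "exon"
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand,
    type = type,
    source = "cnvselscan",
    phase = ifelse(type == "CDS", 0L, NA_integer_),
    ID = ifelse(is_gene, ann$gene_id,
                paste0(ann$gene_id, ":", ann$feature_kind, ":", seq_len(nrow(ann)))),
    Parent = ifelse(is_gene, NA_character_, ann$gene_id)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
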