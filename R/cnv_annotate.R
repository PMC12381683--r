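## Category vocabulary, in precedence order (highest first). A CNV takes the
## highest-precedence category it matches across all overlapped genes.
feature_categories <- c("exonic", "splicing", "UTR5", "UTR3", "ncRNA_exonic",
                        "ncRNA_intronic", "intronic", "upstream", "downstream",
                        "upstream_and_downstream", "intergenic")

#' Assign overlapping genes to variants
#'
#' Gene-body overlap by at least 1 bp (no flank), the rule used for the
#' "not enriched for genes" candidate exclusion.
#'
#' @param x an [sv_set] or a `data.frame` with `chrom`, `pos`, `end`.
#' @param genes a [gene_annotation].
#' @return A list (one element per variant) of sorted gene-id vectors.
#' @export
assign_genes <- function(x, genes) {
  v <- if (inherits(x, "sv_set")) x$variants else x
  bodies <- gene_bodies(genes)
  out <- rep(list(character(0)), nrow(v))
  if (nrow(bodies) == 0 || nrow(v) == 0) return(out)
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$end))
  ggr <- GenomicRanges::GRanges(bodies$chrom,
                                IRanges::IRanges(bodies$start, bodies$end))
  hits <- GenomicRanges::findOverlaps(vgr, ggr)
  hit_list <- split(bodies$gene_id[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
  for (k in names(hit_list)) out[[as.integer(k)]] <- sort(unique(hit_list[[k]]))
  out
}

## derived feature tracks used by the classifier
annotation_tracks <- function(genes, flank_bp) {
  pick <- function(kind) {
    f <- genes[genes$feature_kind %in% kind, , drop = FALSE]
    GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end))
  }
  coding <- genes[genes$feature_kind == "gene", , drop = FALSE]
  nc <- genes[genes$feature_kind == "ncRNA_gene", , drop = FALSE]
  exons <- genes[genes$feature_kind %in% c("exon", "ncRNA_exon"), , drop = FALSE]

  ## splice sites: the 2 bp of each intron adjacent to an exon boundary;
  ## introns are the within-gene gaps between that gene's exons
  splice <- list()
  for (gid in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) next
    int_start <- ex$end[-nrow(ex)] + 1L
    int_end <- ex$start[-1] - 1L
    ok <- int_end >= int_start
    if (!any(ok)) next
    splice[[gid]] <- data.frame(
      chrom = ex$chrom[1],
      start = c(int_start[ok], pmax(int_start[ok], int_end[ok] - 1L)),
      end = c(pmin(int_end[ok], int_start[ok] + 1L), int_end[ok])
    )
  }
  splice <- if (length(splice)) do.call(rbind, splice) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))

  flank <- function(bodies, side) {
    ## side "up": before the transcription start, strand-aware
    if (nrow(bodies) == 0) {
      return(list(gr = GenomicRanges::GRanges(), gene_id = character(0)))
    }
    up_is_left <- bodies$strand == "+"
    left <- (side == "up") == up_is_left
    start <- ifelse(left, pmax(1L, bodies$start - flank_bp), bodies$end + 1L)
    end <- ifelse(left, bodies$start - 1L, bodies$end + flank_bp)
    keep <- end >= start
    list(gr = GenomicRanges::GRanges(bodies$chrom[keep],
                                     IRanges::IRanges(start[keep], end[keep])),
         gene_id = bodies$gene_id[keep])
  }
  bodies <- gene_bodies(genes)
  list(
    cds = pick("CDS"),
    exon = pick(c("exon", "ncRNA_exon")),
    splice = GenomicRanges::GRanges(splice$chrom,
                                    IRanges::IRanges(splice$start, splice$end)),
    utr5 = pick("five_prime_UTR"),
    utr3 = pick("three_prime_UTR"),
    nc_exon = pick("ncRNA_exon"),
    nc_gene = pick("ncRNA_gene"),
    coding_gene = pick("gene"),
    up = flank(bodies, "up"),
    down = flank(bodies, "down"),
    bodies = bodies
  )
}

#' Classify variants by genomic feature
#'
#' Assigns every variant exactly one category under the precedence
#' exonic > splicing > UTR5 > UTR3 > ncRNA_exonic > ncRNA_intronic >
#' intronic > upstream/downstream (a variant in both flanks becomes
#' `upstream_and_downstream`) > intergenic. `exonic` means coding-sequence
#' overlap; `splicing` means overlap of a 2 bp intronic splice site without
#' touching an exon; flanks extend `flank_bp` from the gene ends,
#' strand-aware. The reported genes are the overlapped gene bodies, or the
#' flanked genes for the upstream/downstream categories; only intergenic
#' calls carry no gene.
#'
#' @param sv an [sv_set] (or `data.frame` with `id`, `chrom`, `pos`, `end`).
#' @param genes a [gene_annotation] with sub-features.
#' @param flank_bp flank width in bp (default 1000).
#' @return `data.frame` with `id`, `category` (factor over the full
#'   vocabulary) and `genes` (comma-separated ids, empty for intergenic).
#' @export
classify_features <- function(sv, genes, flank_bp = 1000) {
  v <- if (inherits(sv, "sv_set")) sv$variants else sv
  tr <- annotation_tracks(genes, flank_bp)
  vgr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$end))
  ov <- function(gr) GenomicRanges::countOverlaps(vgr, gr) > 0

  hit_cds <- ov(tr$cds)
  hit_exon <- ov(tr$exon)
  hit_splice <- ov(tr$splice)
  hit_utr5 <- ov(tr$utr5)
  hit_utr3 <- ov(tr$utr3)
  hit_nc_exon <- ov(tr$nc_exon)
  hit_nc_gene <- ov(tr$nc_gene)
  hit_coding <- ov(tr$coding_gene)
  hit_up <- ov(tr$up$gr)
  hit_down <- ov(tr$down$gr)

  category <- rep("intergenic", nrow(v))
  category[hit_up & !hit_down] <- "upstream"
  category[hit_down & !hit_up] <- "downstream"
  category[hit_up & hit_down] <- "upstream_and_downstream"
  category[hit_coding] <- "intronic"
  category[hit_nc_gene] <- "ncRNA_intronic"
  category[hit_nc_exon] <- "ncRNA_exonic"
  category[hit_utr3] <- "UTR3"
  category[hit_utr5] <- "UTR5"
  category[hit_splice & !hit_exon] <- "splicing"
  category[hit_cds] <- "exonic"

  body_genes <- assign_genes(v, genes)
  flank_genes <- function(track) {
    hits <- GenomicRanges::findOverlaps(vgr, track$gr)
    out <- rep(list(character(0)), nrow(v))
    hl <- split(track$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (k in names(hl)) out[[as.integer(k)]] <- hl[[k]]
    out
  }
  up_genes <- flank_genes(tr$up)
  down_genes <- flank_genes(tr$down)
  gene_list <- lapply(seq_len(nrow(v)), function(i) {
    g <- switch(category[i],
      intergenic = character(0),
      upstream = up_genes[[i]],
      downstream = down_genes[[i]],
      upstream_and_downstream = c(up_genes[[i]], down_genes[[i]]),
      body_genes[[i]]
    )
    sort(unique(g))
  })
  data.frame(
    id = v$id,
    category = factor(category, levels = feature_categories),
    genes = vapply(gene_list, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Category proportions of a set of feature calls
#'
#' @param calls output of [classify_features] (>= 1 row).
#' @return `data.frame` with `category` (fixed order) and `proportion`
#'   summing to 1.
#' @export
feature_summary <- function(calls) {
  if (nrow(calls) == 0) stop("no feature calls")
  tab <- table(factor(calls$category, levels = feature_categories))
  data.frame(category = factor(feature_categories, levels = feature_categories),
             count = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab))
}
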