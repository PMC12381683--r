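#' Merge thresholds for population-level SV deduplication
#'
#' Two records collapse when they agree positionally — reciprocal overlap of
#' at least 50% for deletions, 90% for insertions, inversions and
#' duplications — and their population genotype vectors are consistent in at
#' least 95% of samples comparable in both. All thresholds are inclusive.
#' Insertions, which have no genomic span, are instead compared by breakpoint
#' distance (<= `ins_dist` bp) and length ratio (>= `other_overlap`).
#'
#' @param del_overlap reciprocal-overlap threshold for deletions (default 0.5).
#' @param other_overlap threshold for INS/INV/DUP (default 0.9).
#' @param gt_consistency genotype-concordance threshold (default 0.95).
#' @param ins_dist maximum insertion breakpoint distance in bp (default 100).
#' @export
merge_thresholds <- function(del_overlap = 0.5, other_overlap = 0.9,
                             gt_consistency = 0.95, ins_dist = 100) {
  vals <- c(del_overlap, other_overlap, gt_consistency)
  if (any(vals <= 0 | vals > 1)) stop("thresholds must lie in (0, 1]")
  structure(list(del_overlap = del_overlap, other_overlap = other_overlap,
                 gt_consistency = gt_consistency, ins_dist = ins_dist),
            class = "merge_thresholds")
}

#' Reciprocal overlap of two genomic intervals
#'
#' `min(shared / length(a), shared / length(b))` for 1-based inclusive
#' intervals on the same chromosome; 0 when disjoint.
#'
#' @param a,b length-2 numeric vectors `c(start, end)`.
#' @return Overlap fraction in `[0, 1]`.
#' @examples
#' reciprocal_overlap(c(100, 199), c(150, 249))  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  if (a[2] < a[1] || b[2] < b[1]) stop("zero- or negative-length interval")
  shared <- min(a[2], b[2]) - max(a[1], b[1]) + 1
  if (shared <= 0) return(0)
  min(shared / (a[2] - a[1] + 1), shared / (b[2] - b[1] + 1))
}

#' Genotype concordance between two records
#'
#' Fraction of samples, among those non-missing in both records, carrying an
#' identical genotype. Returns 1 when no sample is comparable.
#'
#' @param g1,g2 genotype dosage vectors (0/1/2/`NA`) over the same panel.
#' @export
genotype_concordance <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors over different panels")
  comparable <- !is.na(g1) & !is.na(g2)
  if (!any(comparable)) return(1)
  mean(g1[comparable] == g2[comparable])
}

## pair predicate for records i, j of a common (chrom, svtype) stratum
merge_pair_ok <- function(v, geno, i, j, thresholds) {
  type <- v$svtype[i]
  if (type == "INS") {
    if (abs(v$pos[i] - v$pos[j]) > thresholds$ins_dist) return(FALSE)
    l1 <- abs(v$svlen[i]); l2 <- abs(v$svlen[j])
    if (min(l1, l2) / max(l1, l2) < thresholds$other_overlap) return(FALSE)
  } else {
    thr <- if (type == "DEL") thresholds$del_overlap else thresholds$other_overlap
    ro <- reciprocal_overlap(c(v$pos[i], v$end[i]), c(v$pos[j], v$end[j]))
    if (ro < thr) return(FALSE)
  }
  genotype_concordance(geno[i, ], geno[j, ]) >= thresholds$gt_consistency
}

## union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

## majority vote over a vector of dosages; NA is a category; ties -> NA
majority_genotype <- function(x) {
  key <- ifelse(is.na(x), "NA", as.character(x))
  tab <- table(key)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) != 1 || winners == "NA") return(NA_integer_)
  as.integer(winners)
}

#' Population-level SV merging
#'
#' Within each (chromosome, SV type) stratum, records are clustered by
#' single linkage under the pair predicate of [merge_thresholds] (positional
#' agreement AND genotype concordance). Each cluster is replaced by one
#' representative taking the lower-median start and end and the per-sample
#' majority genotype (ties give a missing genotype); its id is the
#' lexicographically smallest member id. The result is sorted by
#' (chromosome, position) and is invariant to the input record order.
#' Because linkage is transitive, chains can merge pairs that individually
#' sit below the overlap threshold.
#'
#' @param sv an [sv_set] of candidate records (one shared panel).
#' @param thresholds a [merge_thresholds].
#' @return A list with `sv` (merged [sv_set]; `variants` gains `support` and
#'   a comma-separated `members` column) and `clusters` (a long
#'   `data.frame` mapping member ids to cluster representatives).
#' @export
merge_population <- function(sv, thresholds = merge_thresholds()) {
  stopifnot(inherits(sv, "sv_set"), inherits(thresholds, "merge_thresholds"))
  v <- sv$variants
  n <- nrow(v)
  if (n == 0) {
    out <- v
    out$support <- integer(0)
    out$members <- character(0)
    return(list(sv = sv_set(out, sv$geno, sv$panel,
                            chrom_lengths = attr(sv, "chrom_lengths")),
                clusters = data.frame(representative = character(0),
                                      member = character(0))))
  }
  parent <- uf_new(n)
  strata <- split(seq_len(n), paste(v$chrom, v$svtype))
  for (idx in strata) {
    if (length(idx) < 2) next
    type <- v$svtype[idx[1]]
    if (type == "INS") {
      ir <- IRanges::IRanges(v$pos[idx], v$pos[idx])
      hits <- IRanges::findOverlaps(ir, maxgap = thresholds$ins_dist,
                                    drop.self = TRUE, drop.redundant = TRUE)
    } else {
      ir <- IRanges::IRanges(v$pos[idx], v$end[idx])
      hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    }
    qh <- idx[S4Vectors::queryHits(hits)]
    sh <- idx[S4Vectors::subjectHits(hits)]
    for (k in seq_along(qh)) {
      i <- qh[k]; j <- sh[k]
      ri <- uf_find(parent, i); rj <- uf_find(parent, j)
      if (ri == rj) next
      if (merge_pair_ok(v, sv$geno, i, j, thresholds)) {
        parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), roots)

  reps <- lapply(groups, function(g) {
    pos <- median_lower(v$pos[g])
    end <- median_lower(v$end[g])
    type <- v$svtype[g[1]]
    svlen <- if (type == "INS") {
      sign(v$svlen[g[1]]) * median_lower(abs(v$svlen[g]))
    } else {
      (if (type == "DEL") -1L else 1L) * (end - pos + 1L)
    }
    geno <- apply(sv$geno[g, , drop = FALSE], 2, majority_genotype)
    list(variant = data.frame(
      id = min(v$id[g]), chrom = v$chrom[g[1]], pos = pos, end = end,
      svtype = type, svlen = svlen,
      support = length(g),
      members = paste(sort(v$id[g]), collapse = ","),
      stringsAsFactors = FALSE
    ), geno = geno)
  })
  variants <- do.call(rbind, lapply(reps, `[[`, "variant"))
  geno <- do.call(rbind, lapply(reps, `[[`, "geno"))
  ord <- order(variants$chrom, variants$pos, variants$id)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(variants) <- NULL
  merged <- sv_set(variants, geno, sv$panel,
                   chrom_lengths = attr(sv, "chrom_lengths"))
  clusters <- data.frame(
    representative = rep(variants$id, variants$support),
    member = unlist(strsplit(variants$members, ",", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  list(sv = merged, clusters = clusters)
}
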