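#' Simulation configuration for a two-group deletion-CNV cohort
#'
#' Describes a cohort of diploid individuals split into an HL and an LL group,
#' genotyped at `n_variants` biallelic deletion CNVs. Between-group
#' differentiation is generated under the Balding-Nichols model: each
#' variant's ancestral allele frequency is drawn from a (truncated) Beta
#' distribution, and the two group frequencies are Beta draws around it with
#' variance controlled by `target_fst`. Within groups genotypes are
#' Hardy-Weinberg; genotypes are set missing i.i.d. at `missing_rate`.
#'
#' @param n_hl,n_ll diploid sample counts per group (default 15 + 15, the
#'   cohort design emulated throughout).
#' @param n_variants number of CNVs to simulate.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param target_fst differentiation parameter F in `[0, 0.99]`.
#' @param anc_beta two shape parameters of the ancestral-frequency Beta
#'   distribution (default `c(0.8, 0.8)`).
#' @param anc_bounds truncation bounds for ancestral frequencies (default
#'   `[0.05, 0.95]`), keeping most sites polymorphic so the MAF filter is
#'   exercised but not dominant.
#' @param missing_rate genotype-wise i.i.d. missingness fraction in `[0, 1)`.
#' @param len_range CNV length range in bp; lengths are log-uniform on it
#'   (default 1 kb - 100 kb).
#' @param sv_types type(s) to simulate; default `"DEL"` only. Other types are
#'   available solely to exercise type-specific merge thresholds.
#' @param sweep optional [sweep_spec] planting a region of fixed group
#'   frequencies.
#' @param seed integer seed; identical configs give identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_hl = 15, n_ll = 15, n_variants = 2000,
                       chrom_lengths = c(chr1 = 5e7, chr2 = 3e7),
                       target_fst = 0.05,
                       anc_beta = c(0.8, 0.8),
                       anc_bounds = c(0.05, 0.95),
                       missing_rate = 0.05,
                       len_range = c(1e3, 1e5),
                       sv_types = "DEL",
                       sweep = NULL,
                       seed = 1L) {
  stopifnot(n_hl >= 1, n_ll >= 1, n_variants >= 1)
  if (target_fst < 0 || target_fst > 0.99) stop("target_fst must be in [0, 0.99]")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chrom_lengths must be a named vector of positive lengths")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!all(sv_types %in% c("DEL", "INS", "INV", "DUP"))) stop("unknown sv_types")
  if (!is.null(sweep)) {
    if (!inherits(sweep, "sweep_spec")) stop("sweep must be a sweep_spec")
    if (!sweep$chrom %in% names(chrom_lengths)) {
      stop("sweep chromosome not in chrom_lengths")
    }
    if (sweep$end > chrom_lengths[[sweep$chrom]]) {
      stop("sweep region extends beyond its chromosome")
    }
  }
  structure(list(
    n_hl = as.integer(n_hl), n_ll = as.integer(n_ll),
    n_variants = as.integer(n_variants), chrom_lengths = chrom_lengths,
    target_fst = target_fst, anc_beta = anc_beta, anc_bounds = anc_bounds,
    missing_rate = missing_rate, len_range = len_range, sv_types = sv_types,
    sweep = sweep, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Planted-sweep specification
#'
#' Variants whose start breakpoint falls inside `[start, end]` on `chrom`
#' ignore the Balding-Nichols draw and use the given group frequencies
#' directly — a deterministic stand-in for a region under recent directional
#' selection in one group.
#'
#' @param chrom chromosome name.
#' @param start,end region bounds (1-based inclusive), `start < end`.
#' @param hl_freq,ll_freq deletion-allele frequency in HL and LL, in `[0, 1]`.
#' @export
sweep_spec <- function(chrom, start, end, hl_freq, ll_freq) {
  if (start >= end) stop("sweep start must be < end")
  if (hl_freq < 0 || hl_freq > 1 || ll_freq < 0 || ll_freq > 1) {
    stop("sweep frequencies must lie in [0, 1]")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 hl_freq = hl_freq, ll_freq = ll_freq),
            class = "sweep_spec")
}

#' Draw group allele frequencies under the Balding-Nichols model
#'
#' For ancestral frequency p and differentiation F, each group frequency is an
#' independent draw from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is p and
#' whose variance is `p(1-p)F`. With `target_fst = 0` both groups collapse to
#' the ancestral frequency exactly.
#'
#' @param anc_freq ancestral frequency (vectorised), strictly inside (0, 1).
#' @param target_fst F in `[0, 1)`.
#' @param seed optional seed (RNG state is restored afterwards).
#' @return A list with numeric vectors `p_hl` and `p_ll`.
#' @export
draw_pop_freqs <- function(anc_freq, target_fst, seed = NULL) {
  if (any(anc_freq <= 0 | anc_freq >= 1)) {
    stop("anc_freq must be strictly inside (0, 1)")
  }
  if (target_fst < 0 || target_fst >= 1) stop("target_fst must be in [0, 1)")
  if (target_fst == 0) {
    return(list(p_hl = anc_freq, p_ll = anc_freq))
  }
  with_seed(seed, {
    shape1 <- anc_freq * (1 - target_fst) / target_fst
    shape2 <- (1 - anc_freq) * (1 - target_fst) / target_fst
    list(p_hl = stats::rbeta(length(anc_freq), shape1, shape2),
         p_ll = stats::rbeta(length(anc_freq), shape1, shape2))
  })
}

## place n non-overlapping intervals of given lengths uniformly on [1, L]
place_intervals <- function(n, lengths, L) {
  slack <- L - sum(lengths)
  if (n == 0) return(integer(0))
  if (slack < 0) stop("chromosome too small to place the requested intervals")
  gaps <- sort(runif(n, 0, slack))
  starts <- floor(gaps) + cumsum(c(0, lengths[-n])) + 1
  as.integer(starts)
}

#' Simulate a genotyped deletion-CNV cohort
#'
#' Draws variant positions (uniform, non-overlapping per chromosome), lengths
#' (log-uniform on `len_range`), Balding-Nichols group frequencies, and
#' Hardy-Weinberg genotypes within each group, then masks genotypes missing
#' i.i.d. Variants starting inside the configured sweep region use the sweep
#' frequencies instead.
#'
#' @param config a [sim_config].
#' @return A list with elements `sv` (an [sv_set], sorted by chrom and pos)
#'   and `truth` (a `data.frame` with per-variant `p_hl`, `p_ll`, `in_sweep`).
#' @export
simulate_genotype_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_variants
    chroms <- names(config$chrom_lengths)
    ## variants per chromosome, proportional to length (largest remainder)
    share <- config$chrom_lengths / sum(config$chrom_lengths)
    n_per <- floor(share * n)
    rem <- n - sum(n_per)
    if (rem > 0) {
      extra <- order(share * n - n_per, decreasing = TRUE)[seq_len(rem)]
      n_per[extra] <- n_per[extra] + 1
    }

    lens <- as.integer(round(exp(runif(n, log(config$len_range[1]),
                                       log(config$len_range[2])))))
    types <- if (length(config$sv_types) == 1) {
      rep(config$sv_types, n)
    } else {
      sample(config$sv_types, n, replace = TRUE)
    }

    chrom <- rep(chroms, n_per)
    pos <- integer(n)
    idx0 <- 0L
    len_by_chrom <- split(lens, factor(chrom, levels = chroms))
    for (i in seq_along(chroms)) {
      k <- n_per[[i]]
      if (k == 0) next
      pos[idx0 + seq_len(k)] <- place_intervals(k, len_by_chrom[[i]],
                                                config$chrom_lengths[[i]])
      idx0 <- idx0 + k
    }
    end <- ifelse(types == "INS", pos, pos + lens - 1L)
    svlen <- ifelse(types == "DEL", -lens, lens)

    anc <- stats::rbeta(n, config$anc_beta[1], config$anc_beta[2])
    anc <- pmin(pmax(anc, config$anc_bounds[1]), config$anc_bounds[2])
    freqs <- draw_pop_freqs(anc, config$target_fst)
    p_hl <- freqs$p_hl
    p_ll <- freqs$p_ll

    in_sweep <- rep(FALSE, n)
    if (!is.null(config$sweep)) {
      sw <- config$sweep
      in_sweep <- chrom == sw$chrom & pos >= sw$start & pos <= sw$end
      p_hl[in_sweep] <- sw$hl_freq
      p_ll[in_sweep] <- sw$ll_freq
    }

    n_s <- config$n_hl + config$n_ll
    geno <- matrix(NA_integer_, n, n_s)
    geno[, seq_len(config$n_hl)] <- stats::rbinom(n * config$n_hl, 2L, rep(p_hl, config$n_hl))
    geno[, config$n_hl + seq_len(config$n_ll)] <-
      stats::rbinom(n * config$n_ll, 2L, rep(p_ll, config$n_ll))
    if (config$missing_rate > 0) {
      geno[runif(length(geno)) < config$missing_rate] <- NA_integer_
    }

    panel <- sample_panel(
      sprintf("%s%02d", rep(c("HL", "LL"), c(config$n_hl, config$n_ll)),
              c(seq_len(config$n_hl), seq_len(config$n_ll))),
      rep(c("HL", "LL"), c(config$n_hl, config$n_ll))
    )

    ord <- order(factor(chrom, levels = chroms), pos)
    variants <- data.frame(
      id = sprintf("sv%05d", seq_len(n)),
      chrom = chrom[ord], pos = pos[ord], end = end[ord],
      svtype = types[ord], svlen = svlen[ord],
      stringsAsFactors = FALSE
    )
    sv <- sv_set(variants, geno[ord, , drop = FALSE], panel,
                 chrom_lengths = config$chrom_lengths)
    truth <- cbind(variants[, c("id", "chrom", "pos", "end")],
                   data.frame(p_hl = p_hl[ord], p_ll = p_ll[ord],
                              in_sweep = in_sweep[ord]))
    list(sv = sv, truth = truth)
  })
}

#' Fragment a truth set into per-sample callsets
#'
#' Emulates the per-individual caller output that population merging has to
#' reconcile: every sample carrying a variant (dosage >= 1) contributes one
#' record whose interval is shifted by a per-record uniform offset in
#' `[-jitter_bp, jitter_bp]` (capped at a quarter of the variant length so
#' that true duplicates always satisfy the 50% deletion overlap criterion),
#' and records are dropped independently with probability `dropout`. Emitted
#' records keep the full population genotype vector, i.e. they represent the
#' state after cohort-wide re-genotyping.
#'
#' @param sv truth [sv_set].
#' @param jitter_bp maximum breakpoint shift in bp (>= 0).
#' @param dropout per-record drop probability in `[0, 1]`.
#' @param seed optional seed.
#' @return An [sv_set] of per-sample records; `variants$source_sample` names
#'   the emitting sample and `variants$truth_id` the originating variant.
#' @export
fragment_to_callsets <- function(sv, jitter_bp = 0, dropout = 0, seed = NULL) {
  stopifnot(inherits(sv, "sv_set"), jitter_bp >= 0, dropout >= 0, dropout <= 1)
  with_seed(seed, {
    carriers <- which(!is.na(sv$geno) & sv$geno >= 1L, arr.ind = TRUE)
    if (nrow(carriers) > 0 && dropout > 0) {
      keep <- runif(nrow(carriers)) >= dropout
      carriers <- carriers[keep, , drop = FALSE]
    }
    if (nrow(carriers) == 0) {
      empty <- sv$variants[0, ]
      empty$source_sample <- character(0)
      empty$truth_id <- character(0)
      return(sv_set(empty, sv$geno[0, , drop = FALSE], sv$panel,
                    chrom_lengths = attr(sv, "chrom_lengths")))
    }
    vi <- carriers[, 1]
    si <- carriers[, 2]
    v <- sv$variants[vi, , drop = FALSE]
    len <- ifelse(v$svtype == "INS", abs(v$svlen), v$end - v$pos + 1L)
    cap <- pmin(jitter_bp, floor(len / 4))
    offset <- as.integer(round(runif(nrow(v), -cap, cap)))
    v$truth_id <- v$id
    v$source_sample <- sv$panel$sample_id[si]
    v$pos <- v$pos + offset
    v$end <- v$end + offset
    v$id <- paste0(v$truth_id, "_", v$source_sample)
    ord <- order(factor(v$chrom, levels = unique(sv$variants$chrom)), v$pos, v$id)
    sv_set(v[ord, , drop = FALSE], sv$geno[vi[ord], , drop = FALSE], sv$panel,
           chrom_lengths = attr(sv, "chrom_lengths"))
  })
}

#' Simulate a toy gene annotation
#'
#' Places non-overlapping gene models uniformly on the genome. Coding genes
#' carry three exons with CDS and both UTRs; a fraction of genes are ncRNA
#' genes with two ncRNA exons. Deterministic under `seed`.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_genes number of genes (>= 0).
#' @param gene_length gene body length in bp (default 20 kb).
#' @param nc_fraction fraction of genes emitted as ncRNA genes (default 0.2).
#' @param seed integer seed.
#' @return A `gene_annotation` data.frame (see [read_gene_annotation]) with
#'   columns `chrom`, `start`, `end`, `strand`, `gene_id`, `feature_kind`.
#' @export
simulate_annotation <- function(chrom_lengths, n_genes, gene_length = 20000,
                                nc_fraction = 0.2, seed = 1L) {
  stopifnot(n_genes >= 0, gene_length >= 100)
  if (n_genes == 0) {
    return(gene_annotation(data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), gene_id = character(0), feature_kind = character(0),
      stringsAsFactors = FALSE
    )))
  }
  with_seed(seed, {
    chroms <- names(chrom_lengths)
    share <- chrom_lengths / sum(chrom_lengths)
    n_per <- floor(share * n_genes)
    rem <- n_genes - sum(n_per)
    if (rem > 0) {
      extra <- order(share * n_genes - n_per, decreasing = TRUE)[seq_len(rem)]
      n_per[extra] <- n_per[extra] + 1
    }
    if (any(n_per * gene_length > chrom_lengths)) {
      stop("genome too small to place ", n_genes, " genes of ", gene_length, " bp")
    }
    rows <- list()
    g <- 0L
    for (i in seq_along(chroms)) {
      k <- n_per[[i]]
      if (k == 0) next
      starts <- place_intervals(k, rep(gene_length, k), chrom_lengths[[i]])
      for (s in starts) {
        g <- g + 1L
        gid <- sprintf("gene%03d", g)
        strand <- sample(c("+", "-"), 1)
        is_nc <- runif(1) < nc_fraction
        e <- s + gene_length - 1L
        rel <- function(a, b) c(s + round(a * gene_length), s + round(b * gene_length) - 1L)
        if (is_nc) {
          ex1 <- rel(0, 0.2); ex2 <- rel(0.8, 1)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chroms[i],
            start = c(s, ex1[1], ex2[1]),
            end = c(e, ex1[2], min(ex2[2], e)),
            strand = strand, gene_id = gid,
            feature_kind = c("ncRNA_gene", "ncRNA_exon", "ncRNA_exon"),
            stringsAsFactors = FALSE
          )
        } else {
          ex1 <- rel(0, 0.10); ex2 <- rel(0.45, 0.55); ex3 <- rel(0.90, 1)
          utr_lo <- rel(0, 0.04)           # UTR at the low-coordinate end
          utr_hi <- rel(0.96, 1)           # UTR at the high-coordinate end
          cds1 <- c(utr_lo[2] + 1L, ex1[2])
          cds3 <- c(ex3[1], utr_hi[1] - 1L)
          utr5 <- if (strand == "+") utr_lo else utr_hi
          utr3 <- if (strand == "+") utr_hi else utr_lo
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chroms[i],
            start = c(s, ex1[1], ex2[1], ex3[1], cds1[1], ex2[1], cds3[1], utr5[1], utr3[1]),
            end = c(e, ex1[2], ex2[2], min(ex3[2], e), cds1[2], ex2[2], cds3[2],
                    utr5[2], min(utr3[2], e)),
            strand = strand, gene_id = gid,
            feature_kind = c("gene", "exon", "exon", "exon", "CDS", "CDS", "CDS",
                             "five_prime_UTR", "three_prime_UTR"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    ann <- do.call(rbind, rows)
    ann <- ann[order(factor(ann$chrom, levels = chroms), ann$start,
                     ann$feature_kind), ]
    rownames(ann) <- NULL
    gene_annotation(ann)
  })
}
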