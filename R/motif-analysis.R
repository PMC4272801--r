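# Coverage and conservation analyses of motif occurrences outside repeats.

# stranded weighted per-base coverage pileup from alignments;
# returns keyed data.table(chrom, strand, pos, w)
alignment_coverage <- function(aln) {
  bl <- alignment_blocks(aln)
  if (nrow(bl) == 0L) {
    cov <- data.table::data.table(chrom = character(0), strand = character(0),
                                  pos = integer(0), w = numeric(0))
    data.table::setkey(cov, chrom, strand, pos)
    return(cov)
  }
  lens <- bl$end - bl$start + 1L
  cov <- data.table::data.table(
    chrom = rep(bl$chrom, lens), strand = rep(bl$strand, lens),
    pos = sequence(lens, from = bl$start), w = rep(bl$weight, lens))
  cov <- cov[, .(w = sum(w)), by = .(chrom, strand, pos)]
  data.table::setkey(cov, chrom, strand, pos)
  cov
}

# mean coverage over a set of (chrom, strand, pos) queries; absent bases = 0
mean_coverage_at <- function(cov, chrom, strand, pos) {
  if (length(pos) == 0L) return(NA_real_)
  q <- data.table::data.table(chrom = chrom, strand = strand, pos = pos)
  hit <- cov[q, on = c("chrom", "strand", "pos")]
  vals <- hit$w
  vals[is.na(vals)] <- 0
  mean(vals)
}

#' Coverage at motif occurrences versus their flanks
#'
#' For every TESM, compares the mean weighted CLIP coverage over the bases of
#' its nonrepetitive occurrences with the mean over the surrounding `flank`
#' nucleotides (half on each side, motif excluded, truncated at contig edges).
#' Mirrors the "coverage at the motif versus the surrounding 200 nucleotides"
#' comparison used to show that TE-derived motifs are bound outside repeats.
#'
#' @param occurrences occurrence table from [scan_transcriptome()].
#' @param alignments CLIP alignment table.
#' @param flank total flank width (default 200).
#' @param chrom_lengths named chromosome lengths (for edge truncation).
#' @return list with `per_tesm` (tesm_id, motif_mean, flank_mean, increased)
#'   and `fraction` (share of TESMs with motif coverage above flank; `NA`
#'   when there is no coverage at all).
#' @export
motif_vs_flank_coverage <- function(occurrences, alignments, flank = 200L,
                                    chrom_lengths = NULL) {
  occ <- data.table::as.data.table(occurrences)[in_repeat == FALSE]
  cov <- alignment_coverage(alignments)
  if (nrow(cov) == 0L || nrow(occ) == 0L) {
    return(list(per_tesm = data.table::data.table(
      tesm_id = character(0), motif_mean = numeric(0),
      flank_mean = numeric(0), increased = logical(0)), fraction = NA_real_))
  }
  half <- flank %/% 2L
  res <- occ[, {
    mq <- list(); fq <- list()
    for (i in seq_len(.N)) {
      mpos <- start[i]:end[i]
      lo <- start[i] - half; hi <- end[i] + half
      lo <- max(1L, lo)
      if (!is.null(chrom_lengths)) hi <- min(hi, chrom_lengths[[chrom[i]]])
      fpos <- setdiff(lo:hi, mpos)
      mq[[i]] <- data.table::data.table(chrom = chrom[i], strand = strand[i],
                                        pos = mpos)
      fq[[i]] <- data.table::data.table(chrom = chrom[i], strand = strand[i],
                                        pos = fpos)
    }
    mq <- data.table::rbindlist(mq); fq <- data.table::rbindlist(fq)
    .(motif_mean = mean_coverage_at(cov, mq$chrom, mq$strand, mq$pos),
      flank_mean = mean_coverage_at(cov, fq$chrom, fq$strand, fq$pos))
  }, by = tesm_id]
  res[, increased := motif_mean > flank_mean]
  list(per_tesm = res[], fraction = mean(res$increased))
}

#' Conservation of motif occurrences by annotation class
#'
#' For occurrences of one annotation class outside repeats: per-TESM median of
#' the occurrence-mean track scores; per-motif-position score medians
#' (position 1 = motif 5' end); and a position-matched random-9-mer null:
#' `n_null` sets of windows sampled uniformly from the same class space, each
#' summarised by the median of its window means.
#'
#' @param occurrences occurrence table from [scan_transcriptome()].
#' @param track a `score_track` (e.g. conservation scores).
#' @param class annotation class to analyse (`"intron"`, `"3'UTR"`,
#'   `"lncRNA"`; coding sequence is conventionally excluded from this
#'   analysis).
#' @param isoforms exon/CDS table (defines the class interval space for the
#'   null).
#' @param te_instances TE instances; random windows overlapping them are
#'   excluded, matching the nonrepetitive occurrence set.
#' @param n_null random window sets (default 1000).
#' @param seed RNG seed for the null sampling.
#' @return list with `per_tesm` (tesm_id, median_score, n_occ), `per_position`
#'   (matrix TESM x 9 of position medians), `null_medians` (length `n_null`),
#'   and `n_skipped` (occurrences without any track coverage).
#' @export
conservation_summary <- function(occurrences, track, class, isoforms,
                                 te_instances = NULL, n_null = 1000L,
                                 seed = 1L) {
  occ <- data.table::as.data.table(occurrences)
  .cls <- class
  occ <- occ[occ$in_repeat == FALSE & occ$class == .cls]
  empty <- list(per_tesm = data.table::data.table(
    tesm_id = character(0), median_score = numeric(0), n_occ = integer(0)),
    per_position = matrix(numeric(0), 0, 9), null_medians = numeric(0),
    n_skipped = 0L)
  if (nrow(occ) == 0L) return(empty)
  w <- occ$end[1L] - occ$start[1L] + 1L
  # per-occurrence score vectors, 5'->3' along the motif
  mat <- matrix(NA_real_, nrow(occ), w)
  for (i in seq_len(nrow(occ))) {
    pos <- occ$start[i]:occ$end[i]
    if (occ$strand[i] == "-") pos <- rev(pos)
    mat[i, ] <- track_values(track, occ$chrom[i], pos)
  }
  covered <- rowSums(!is.na(mat)) > 0L
  n_skipped <- sum(!covered)
  occ <- occ[covered]
  mat <- mat[covered, , drop = FALSE]
  if (nrow(occ) == 0L) { empty$n_skipped <- n_skipped; return(empty) }
  occ_mean <- rowMeans(mat, na.rm = TRUE)
  per_tesm <- data.table::data.table(tesm_id = occ$tesm_id,
                                     ms = occ_mean)[,
    .(median_score = stats::median(ms), n_occ = .N), by = tesm_id]
  tes <- unique(occ$tesm_id)
  per_position <- t(vapply(tes, function(id) {
    apply(mat[occ$tesm_id == id, , drop = FALSE], 2L,
          stats::median, na.rm = TRUE)
  }, numeric(w)))
  rownames(per_position) <- tes

  # position-matched random 9-mer null from the same class space
  cls <- annotation_class_intervals(isoforms)[[class]]
  null_medians <- numeric(0)
  if (!is.null(cls) && nrow(cls)) {
    cls <- data.table::as.data.table(cls)
    if (!is.null(te_instances)) {
      te <- data.table::as.data.table(te_instances)[, .(chrom, start, end)]
      cls <- subtract_intervals(cls, te)
    }
    cls <- cls[end - start + 1L >= w]
    if (nrow(cls)) {
      lens <- cls$end - cls$start - w + 2L
      null_medians <- with_seed(seed, {
        k <- nrow(occ)
        vapply(seq_len(n_null), function(s) {
          iv <- sample.int(nrow(cls), k, replace = TRUE, prob = lens)
          st <- cls$start[iv] + floor(runif(k) * lens[iv])
          means <- vapply(seq_len(k), function(i) {
            mean(track_values(track, cls$chrom[iv[i]],
                              st[i]:(st[i] + w - 1L)), na.rm = TRUE)
          }, numeric(1))
          stats::median(means, na.rm = TRUE)
        }, numeric(1))
      })
    }
  }
  list(per_tesm = per_tesm[], per_position = per_position,
       null_medians = null_medians, n_skipped = n_skipped)
}
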