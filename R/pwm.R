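# Position weight matrix scanning with exact p-values, the
# information-coverage Euclidean motif distance, and motif clustering.

#' Integer-binned log-odds score matrix for a PWM
#'
#' Scores are `log2(p / bg)` discretised to `binwidth` bins (default 1e-3).
#' The same binned scores are used by the scanner and by the exact tail
#' distribution, so scan scores and p-values refer to one common scale.
#'
#' @param pwm 4 x n column-normalised matrix with rows A/C/G/T.
#' @param bg background nucleotide probabilities (named, A/C/G/T); default
#'   uniform.
#' @param binwidth score discretisation (default 1e-3).
#' @return 4 x n integer matrix of binned scores.
#' @export
pwm_score_bins <- function(pwm, bg = NULL, binwidth = 1e-3) {
  bg <- bg %||% c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg <- bg[rownames(pwm)]
  m <- log2(sweep(pwm, 1L, bg, "/"))
  matrix(as.integer(round(m / binwidth)), nrow(pwm), ncol(pwm),
         dimnames = dimnames(pwm))
}

#' Exact tail distribution of PWM scores under a 0-order background
#'
#' Convolves the per-column binned-score distributions by dynamic programming
#' and returns the exact upper-tail probability for every achievable score
#' bin.
#'
#' @inheritParams pwm_score_bins
#' @return list with `bins` (ascending integer score bins), `prob` (point
#'   mass), `tail` (P(score >= bin)), and `binwidth`.
#' @export
pwm_tail_distribution <- function(pwm, bg = NULL, binwidth = 1e-3) {
  bg <- bg %||% c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg <- bg[rownames(pwm)]
  sb <- pwm_score_bins(pwm, bg, binwidth)
  # dist over offset..offset+len-1 as a prob vector
  off <- 0L; p <- 1
  for (j in seq_len(ncol(sb))) {
    s <- sb[, j]
    new_lo <- off + min(s)
    new_hi <- off + length(p) - 1L + max(s)
    np <- numeric(new_hi - new_lo + 1L)
    for (b in seq_len(4L)) {
      sh <- (off + s[b]) - new_lo
      idx <- seq_along(p) + sh
      np[idx] <- np[idx] + p * bg[b]
    }
    p <- np; off <- new_lo
  }
  bins <- seq.int(off, off + length(p) - 1L)
  keep <- p > 0
  bins <- bins[keep]; p <- p[keep]
  tail <- rev(cumsum(rev(p)))
  list(bins = bins, prob = p, tail = tail, binwidth = binwidth)
}

#' Exact p-value of a binned PWM score
#'
#' @param dist tail distribution from [pwm_tail_distribution()].
#' @param score_bin integer score bin(s).
#' @return P(score >= score_bin) under the background.
#' @export
pwm_score_pvalue <- function(dist, score_bin) {
  idx <- findInterval(score_bin - 1L, dist$bins) + 1L
  out <- numeric(length(score_bin))
  inside <- idx <= length(dist$bins)
  out[inside] <- dist$tail[idx[inside]]
  out[!inside] <- 0
  out[score_bin <= dist$bins[1L]] <- 1
  out
}

# numeric scan of one sequence (character string) with a binned score matrix;
# returns integer scores at every start position (NA where the window holds N)
scan_scores <- function(seq, sb) {
  n <- nchar(seq)
  w <- ncol(sb)
  if (n < w) return(integer(0))
  code <- match(str_chars(seq), c("A", "C", "G", "T"))
  ns <- n - w + 1L
  total <- rep(0L, ns)
  bad <- rep(FALSE, ns)
  for (j in seq_len(w)) {
    cj <- code[j:(j + ns - 1L)]
    nas <- is.na(cj)
    bad <- bad | nas
    cj[nas] <- 1L
    total <- total + sb[cbind(cj, j)]
  }
  total[bad] <- NA_integer_
  total
}

#' Scan the transcriptome for motif occurrences with exact p-values
#'
#' Scans merged gene spans on their strand with each TESM's log-odds matrix
#' (0-order background from the scanned sequence space), retains positions
#' with exact p-value at most `p_max`, flags occurrences overlapping TE
#' instances, and annotates each occurrence with the most specific annotation
#' class it touches (precedence CDS > 3'UTR > lncRNA > intron).
#'
#' @param tesms a `tesm_set` (or a named list of 4 x 9 PWMs).
#' @param genome genome sequences.
#' @param isoforms exon/CDS table.
#' @param te_instances TE instance table (for the `in_repeat` flag); may be
#'   `NULL`.
#' @param p_max p-value threshold (default 1e-5).
#' @param bg optional background probabilities; default estimated from the
#'   scanned space.
#' @return data.table of occurrences: tesm_id, chrom, start, end, strand,
#'   score (log2 odds), p_value, class (CDS/3'UTR/lncRNA/intron), in_repeat.
#' @export
scan_transcriptome <- function(tesms, genome, isoforms, te_instances = NULL,
                               p_max = 1e-5, bg = NULL) {
  pwms <- if (inherits(tesms, "tesm_set")) tesms$pwms else tesms
  if (!length(pwms)) {
    return(empty_occurrences())
  }
  iso <- data.table::as.data.table(isoforms)
  spans <- iso[feature == "exon",
               .(start = min(start), end = max(end)),
               by = .(chrom, strand, gene_id)]
  # merge overlapping gene spans per chrom+strand
  data.table::setorder(spans, chrom, strand, start)
  spans[, grp := cumsum(c(1L, pmax(0L, start[-1L] - cummax(end)[-.N] - 1L)) > 0L),
        by = .(chrom, strand)]
  reg <- spans[, .(start = min(start), end = max(end)),
               by = .(chrom, strand, grp)]
  seqs <- character(nrow(reg))
  for (r in seq_len(nrow(reg))) {
    s <- substr(chrom_string(genome, reg$chrom[r]), reg$start[r], reg$end[r])
    seqs[r] <- if (reg$strand[r] == "-") revcomp(s) else s
  }
  if (is.null(bg)) {
    cnt <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(seqs))[, c("A", "C", "G", "T"), drop = FALSE])
    bg <- cnt / sum(cnt)
  }
  cls <- annotation_class_intervals(iso)
  tq <- if (!is.null(te_instances))
    data.table::as.data.table(te_instances) else NULL
  out <- list()
  for (id in names(pwms)) {
    pwm <- pwms[[id]]
    sb <- pwm_score_bins(pwm, bg)
    dist <- pwm_tail_distribution(pwm, bg)
    thr_i <- which(dist$tail <= p_max)
    if (!length(thr_i)) next
    thr <- dist$bins[thr_i[1L]]
    for (r in seq_len(nrow(reg))) {
      sc <- scan_scores(seqs[r], sb)
      hit <- which(!is.na(sc) & sc >= thr)
      if (!length(hit)) next
      w <- ncol(pwm)
      if (reg$strand[r] == "+") {
        gs <- reg$start[r] + hit - 1L
      } else {
        gs <- reg$end[r] - (hit + w - 1L) + 1L
      }
      out[[length(out) + 1L]] <- data.table::data.table(
        tesm_id = id, chrom = reg$chrom[r], start = gs, end = gs + w - 1L,
        strand = reg$strand[r],
        score = sc[hit] * dist$binwidth,
        p_value = pwm_score_pvalue(dist, sc[hit]))
    }
  }
  if (!length(out)) return(empty_occurrences())
  occ <- data.table::rbindlist(out)
  occ <- unique(occ, by = c("tesm_id", "chrom", "start", "strand"))
  occ[, in_repeat := FALSE]
  if (!is.null(tq) && nrow(tq)) {
    data.table::setkey(tq, chrom, start, end)
    q <- occ[, .(chrom, start, end)]
    q[, qi := .I]
    data.table::setkey(q, chrom, start, end)
    hit <- data.table::foverlaps(q, tq, type = "any", nomatch = NULL)
    occ$in_repeat[unique(hit$qi)] <- TRUE
  }
  occ[, class_ := classify_positions(occ, cls)]
  data.table::setnames(occ, "class_", "class")
  data.table::setorder(occ, tesm_id, chrom, start)
  occ[]
}

empty_occurrences <- function() {
  data.table::data.table(
    tesm_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), score = numeric(0),
    p_value = numeric(0), in_repeat = logical(0), class = character(0))
}

# interval sets per annotation class (CDS, 3'UTR, lncRNA exon, intron space)
annotation_class_intervals <- function(iso) {
  iso <- data.table::as.data.table(iso)
  cds <- iso[feature == "CDS", .(chrom, start, end)]
  mex <- iso[feature == "exon" & is_pre_rna == FALSE & biotype == "mRNA",
             .(chrom, start, end)]
  utr <- subtract_intervals(mex, cds)
  lnc <- iso[feature == "exon" & is_pre_rna == FALSE & biotype == "lncRNA",
             .(chrom, start, end)]
  spans <- iso[feature == "exon", .(start = min(start), end = max(end)),
               by = .(gene_id, chrom)][, .(chrom, start, end)]
  list(CDS = cds, `3'UTR` = utr, lncRNA = lnc, intron = spans)
}

# interval difference a \ b, per chromosome (both 1-based closed)
subtract_intervals <- function(a, b) {
  a <- data.table::as.data.table(a); b <- data.table::as.data.table(b)
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  out <- list()
  for (cn in unique(a$chrom)) {
    av <- a[chrom == cn]; bv <- b[chrom == cn]
    if (nrow(bv) == 0L) { out[[length(out) + 1L]] <- av; next }
    data.table::setorder(bv, start)
    for (i in seq_len(nrow(av))) {
      s <- av$start[i]; e <- av$end[i]
      cur <- s
      for (j in seq_len(nrow(bv))) {
        if (bv$end[j] < cur || bv$start[j] > e) next
        if (bv$start[j] > cur)
          out[[length(out) + 1L]] <- data.table::data.table(
            chrom = cn, start = cur, end = bv$start[j] - 1L)
        cur <- max(cur, bv$end[j] + 1L)
        if (cur > e) break
      }
      if (cur <= e)
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = cn, start = cur, end = e)
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0)))
  data.table::rbindlist(out)
}

# classify occurrence rows by precedence over class interval sets
classify_positions <- function(occ, cls) {
  res <- rep(NA_character_, nrow(occ))
  q <- data.table::data.table(chrom = occ$chrom, start = occ$start,
                              end = occ$end, qi = seq_len(nrow(occ)))
  data.table::setkey(q, chrom, start, end)
  for (nm in c("intron", "lncRNA", "3'UTR", "CDS")) {   # ascending precedence
    iv <- cls[[nm]]
    if (is.null(iv) || nrow(iv) == 0L) next
    iv <- data.table::as.data.table(iv)
    data.table::setkey(iv, chrom, start, end)
    hit <- data.table::foverlaps(q, iv, type = "any", nomatch = NULL)
    res[unique(hit$qi)] <- nm
  }
  res
}

#' Information coverage of PWM columns
#'
#' `1 - H/2` with the Shannon entropy H in bits: 0 for a uniform column, 1
#' for a point mass.
#'
#' @param pwm 4 x n column-normalised matrix.
#' @return numeric vector of per-column information coverages.
#' @export
pwm_info_coverage <- function(pwm) {
  apply(pwm, 2L, function(p) {
    p <- p[p > 0]
    1 - sum(-p * log2(p)) / 2
  })
}

#' Information-coverage-weighted Euclidean distance between PWMs
#'
#' Over all ungapped offsets aligning at least `min_overlap` columns, the
#' distance is the minimum of
#' `sum_i w_i * ||p_i - q_i||_2 / sum_i w_i` with
#' `w_i = sqrt(ic_a(i) * ic_b(i))` (information coverages), so informative
#' columns dominate. If every aligned column pair is uninformative (all
#' weights zero), the unweighted mean distance is used and the result is
#' flagged (`attr(, "flagged")`).
#'
#' @param pwm_a,pwm_b column-normalised 4 x n matrices.
#' @param min_overlap minimum aligned columns (default 5).
#' @param combine how to combine the two columns' information coverages:
#'   `"sqrt"` (geometric mean, default), `"min"`, or `"product"`.
#' @return nonnegative distance with attributes `offset` and `flagged`.
#' @export
motif_distance <- function(pwm_a, pwm_b, min_overlap = 5L,
                           combine = c("sqrt", "min", "product")) {
  combine <- match.arg(combine)
  na <- ncol(pwm_a); nb <- ncol(pwm_b)
  ica <- pwm_info_coverage(pwm_a); icb <- pwm_info_coverage(pwm_b)
  best <- Inf; best_off <- 0L; best_flag <- FALSE
  for (d in seq(-(na - min_overlap), nb - min_overlap)) {
    i1 <- max(1L, 1L - d); i2 <- min(na, nb - d)
    if (i2 - i1 + 1L < min_overlap) next
    ii <- i1:i2
    jj <- ii + d
    dcol <- sqrt(colSums((pwm_a[, ii, drop = FALSE] -
                            pwm_b[, jj, drop = FALSE])^2))
    w <- switch(combine,
                sqrt = sqrt(ica[ii] * icb[jj]),
                min = pmin(ica[ii], icb[jj]),
                product = ica[ii] * icb[jj])
    if (sum(w) > 0) {
      val <- sum(w * dcol) / sum(w); flag <- FALSE
    } else {
      val <- mean(dcol); flag <- TRUE
    }
    # ties prefer an informative (weighted) alignment over a flagged one
    if (val < best || (val == best && best_flag && !flag)) {
      best <- val; best_off <- d; best_flag <- flag
    }
  }
  structure(best, offset = best_off, flagged = best_flag)
}

#' Collapse redundant TESMs by clustering and rank the representatives
#'
#' Computes all pairwise [motif_distance()]s, performs average-linkage
#' hierarchical clustering, flattens the dendrogram at height `flatten`,
#' keeps the member with maximal enrichment (ties: maximal support) of each
#' cluster, and returns the representatives ranked by enrichment, truncated
#' to `top_n`.
#'
#' @param tesms a `tesm_set`.
#' @param flatten dendrogram cut height (default 0.15).
#' @param top_n maximum number of representatives (default 300).
#' @param min_overlap,combine passed to [motif_distance()].
#' @return a `tesm_set` of representatives; `meta` gains `cluster` and `rank`.
#' @export
cluster_and_rank <- function(tesms, flatten = 0.15, top_n = 300L,
                             min_overlap = 5L, combine = "sqrt") {
  stopifnot(inherits(tesms, "tesm_set"))
  n <- nrow(tesms$meta)
  if (n == 0L) return(tesms)
  meta <- data.table::copy(tesms$meta)
  if (n == 1L) {
    meta[, `:=`(cluster = 1L, rank = 1L)]
    return(structure(list(meta = meta, pwms = tesms$pwms),
                     class = "tesm_set"))
  }
  ids <- meta$tesm_id
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- as.numeric(
      motif_distance(tesms$pwms[[ids[i]]], tesms$pwms[[ids[j]]],
                     min_overlap = min_overlap, combine = combine))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- if (flatten <= 0) seq_len(n) else stats::cutree(hc, h = flatten)
  meta[, cluster := cl]
  data.table::setorder(meta, cluster, -enrichment, -support, tesm_id)
  reps <- meta[, .SD[1L], by = cluster]
  data.table::setorder(reps, -enrichment, -support, tesm_id)
  reps[, rank := .I]
  reps <- reps[rank <= top_n]
  structure(list(meta = reps, pwms = tesms$pwms[reps$tesm_id]),
            class = "tesm_set")
}
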