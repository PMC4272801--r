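# Isoform-aware Poisson scan-statistic peak calling with mappability
# filtering.

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, computed through the regularized
#' incomplete gamma function (`P(X >= k) = P(Gamma(k, 1) <= lambda)`), which
#' is stable for small tail probabilities.
#'
#' @param k observed count(s), nonnegative integers.
#' @param lambda Poisson rate(s), > 0.
#' @return upper-tail probability, vectorised over `k`/`lambda`.
#' @export
poisson_upper_tail <- function(k, lambda) {
  if (any(lambda <= 0)) stopf("lambda must be > 0")
  if (any(k < 0) || any(k != floor(k))) stopf("k must be a nonnegative integer")
  n <- max(length(k), length(lambda))
  k <- rep_len(k, n); lambda <- rep_len(lambda, n)
  out <- numeric(n)
  out[k == 0] <- 1
  nz <- k > 0
  out[nz] <- stats::pgamma(lambda[nz], shape = k[nz], lower.tail = TRUE)
  out
}

#' Low-mappability flags from genome-wide k-mer multiplicity
#'
#' A base is flagged when the k-mer starting there occurs more than `max_hits`
#' times genome-wide (both strands counted), mirroring the aligner's
#' 20-placement cap: reads from such positions cannot be attributed usefully.
#'
#' @param genome genome sequences.
#' @param k k-mer length (default 20, the aligner seed length).
#' @param max_hits occurrence threshold (default 20).
#' @return named list of per-chromosome logical vectors (TRUE = low
#'   mappability); positions within k-1 of the 3' end are never flagged.
#' @export
build_mappability_track <- function(genome, k = 20L, max_hits = 20L) {
  cl <- chrom_lengths(genome)
  fw <- lapply(names(cl), function(cn)
    encode_kmers(chrom_string(genome, cn), k) %||% numeric(0))
  names(fw) <- names(cl)
  rc <- lapply(names(cl), function(cn)
    encode_kmers(revcomp(chrom_string(genome, cn)), k) %||% numeric(0))
  all_codes <- c(unlist(fw, use.names = FALSE), unlist(rc, use.names = FALSE))
  cnt <- data.table::data.table(kmer = all_codes)[!is.na(kmer), .N, by = kmer]
  data.table::setkey(cnt, kmer)
  flags <- lapply(names(cl), function(cn) {
    v <- rep(FALSE, cl[[cn]])
    codes <- fw[[cn]]
    if (length(codes)) {
      hits <- cnt[data.table::data.table(kmer = codes), on = "kmer"]$N
      v[seq_along(codes)] <- !is.na(hits) & hits > max_hits
    }
    v
  })
  names(flags) <- names(cl)
  flags
}

#' Call peaks with an isoform-aware Poisson scan statistic
#'
#' Slides stranded 30-nt windows (step `step`) over the spans of expressed
#' genes; each window's expected weighted read-start count is the sum over
#' overlapping isoforms of `mass_i * window / length_i` (pre-RNA isoforms make
#' introns testable). Window p-values are Poisson upper tails on the
#' rounded-up weighted count, BH-adjusted across all windows; windows with
#' `q <= alpha` are merged when overlapping or book-ended. Peaks with at least
#' half their bases flagged low-mappability are removed. Each peak is assigned
#' its containing gene (ties: most expressed), a site class (TE family
#' overlapping the peak summit, else "nonrepetitive") and a region (exon if
#' the peak overlaps any spliced exon, else intron).
#'
#' @param alignments duplicate-capped weighted alignment table.
#' @param isoforms pre-RNA-augmented exon table.
#' @param model `abundance_model` estimated from the same alignments.
#' @param te_instances TE instance table (optional; without it all peaks are
#'   nonrepetitive).
#' @param mappability per-chromosome logical flags from
#'   [build_mappability_track()]; `NULL` emits unfiltered peaks with a
#'   warning.
#' @param alpha BH q-value threshold (default 0.01).
#' @param window window width in nt (default 30).
#' @param step window step in nt (default 5).
#' @return data.table of peaks: chrom, start, end, strand, k, lambda, p_value,
#'   q_value, gene_id, site_class, region, alu.
#' @export
call_peaks <- function(alignments, isoforms, model, te_instances = NULL,
                       mappability = NULL, alpha = 0.01, window = 30L,
                       step = 5L) {
  stopifnot(inherits(model, "abundance_model"))
  aln <- data.table::as.data.table(alignments)
  iso <- data.table::as.data.table(isoforms)
  mi <- data.table::as.data.table(model$isoforms)
  empty <- data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), k = numeric(0), lambda = numeric(0),
    p_value = numeric(0), q_value = numeric(0), gene_id = character(0),
    site_class = character(0), region = character(0), alu = logical(0))
  expressed <- mi[mass > 0, unique(gene_id)]
  if (!length(expressed)) return(empty)
  spans <- iso[feature == "exon" & gene_id %in% expressed,
               .(chrom = chrom[1], strand = strand[1],
                 start = min(start), end = max(end)), by = gene_id]
  spans <- spans[end - start + 1L >= window]
  if (nrow(spans) == 0L) return(empty)

  # windows
  wins <- spans[, {
    st <- seq.int(start, end - window + 1L, by = step)
    .(start = st, end = st + window - 1L, chrom = chrom[1], strand = strand[1])
  }, by = gene_id]
  wins[, win_id := .I]

  # weighted read starts per window (stranded)
  starts <- aln[, .(w = sum(weight)), by = .(chrom, strand, pos)]
  starts[, `:=`(start = pos, end = pos)]
  data.table::setkey(starts, chrom, start, end)
  wq <- wins[, .(win_id, chrom, strand, start, end)]
  data.table::setkey(wq, chrom, start, end)
  ovk <- data.table::foverlaps(wq, starts, type = "any", nomatch = NULL)
  ovk <- ovk[strand == i.strand]
  kcount <- ovk[, .(k = sum(w)), by = win_id]
  wins[, k := 0]
  wins[kcount$win_id, k := kcount$k]

  # lambda: sum over isoforms whose exons overlap the window
  ex <- iso[feature == "exon", .(isoform_id, chrom, start, end)]
  data.table::setkey(ex, chrom, start, end)
  ovl <- data.table::foverlaps(wq, ex, type = "any", nomatch = NULL)
  ovl <- unique(ovl[, .(win_id, isoform_id)])
  ovl <- merge(ovl, mi[, .(isoform_id, mass, length)], by = "isoform_id")
  lam <- ovl[, .(lambda = sum(mass * window / length)), by = win_id]
  wins[, lambda := 0]
  wins[lam$win_id, lambda := lam$lambda]
  wins <- wins[lambda > 0]
  if (nrow(wins) == 0L) return(empty)
  wins[, p_value := poisson_upper_tail(ceiling(k), lambda)]
  wins[, q_value := stats::p.adjust(p_value, method = "BH")]
  sig <- wins[q_value <= alpha]
  attr_out <- list(n_windows = nrow(wins), n_enriched = nrow(sig))
  if (nrow(sig) == 0L) {
    data.table::setattr(empty, "window_stats", attr_out)
    return(empty)
  }

  # merge overlapping or book-ended significant windows per chrom+strand
  data.table::setorder(sig, chrom, strand, start)
  sig[, grp := cumsum(c(1L, pmax(0L, start[-1L] - cummax(end)[-.N] - 1L) > 0L)),
      by = .(chrom, strand)]
  peaks <- sig[, .(start = min(start), end = max(end),
                   lambda = sum(lambda), q_value = min(q_value),
                   p_value = min(p_value)),
               by = .(chrom, strand, grp)]
  peaks[, grp := NULL]

  # recount weighted starts in merged spans
  data.table::setkey(peaks, chrom, start, end)
  pq <- data.table::copy(peaks)[, pid := .I]
  data.table::setkey(pq, chrom, start, end)
  ovp <- data.table::foverlaps(pq, starts, type = "any", nomatch = NULL)
  ovp <- ovp[strand == i.strand]
  kk <- ovp[, .(k = sum(w)), by = pid]
  peaks[, k := 0]
  peaks[kk$pid, k := kk$k]

  # mappability filter
  if (is.null(mappability)) {
    warnf("no mappability track supplied; peaks emitted unfiltered")
  } else {
    frac <- vapply(seq_len(nrow(peaks)), function(i) {
      v <- mappability[[peaks$chrom[i]]]
      mean(v[peaks$start[i]:min(peaks$end[i], length(v))])
    }, numeric(1))
    peaks <- peaks[frac < 0.5]
  }
  if (nrow(peaks) == 0L) {
    data.table::setattr(empty, "window_stats", attr_out)
    return(empty)
  }

  # gene assignment: containing span, ties to the most expressed gene
  gmass <- mi[, .(gmass = sum(mass)), by = gene_id]
  spans2 <- merge(spans, gmass, by = "gene_id")
  data.table::setkey(spans2, chrom, start, end)
  pq <- data.table::copy(peaks)[, pid := .I]
  data.table::setkey(pq, chrom, start, end)
  ovg <- data.table::foverlaps(pq, spans2, type = "any", nomatch = NA)
  ovg <- ovg[is.na(strand) | strand == i.strand]
  data.table::setorder(ovg, pid, -gmass)
  gassign <- ovg[, .SD[1L], by = pid]
  peaks[, gene_id := gassign[order(pid)]$gene_id]

  # summit: base of maximal weighted full coverage inside the peak
  cov <- alignment_coverage(aln)
  peaks[, summit := {
    vapply(seq_len(.N), function(i) {
      sel <- cov[.(chrom[i], strand[i])][pos >= start[i] & pos <= end[i]]
      if (nrow(sel) == 0L || all(is.na(sel$w))) return(start[i])
      sel$pos[which.max(sel$w)]
    }, integer(1))
  }]

  # site class from the TE instance overlapping the summit
  peaks[, site_class := "nonrepetitive"]
  if (!is.null(te_instances)) {
    te <- data.table::as.data.table(te_instances)
    data.table::setkey(te, chrom, start, end)
    sq <- peaks[, .(chrom, start = summit, end = summit, pid = .I)]
    data.table::setkey(sq, chrom, start, end)
    ovt <- data.table::foverlaps(sq, te, type = "any", nomatch = NULL)
    data.table::setorder(ovt, pid, start)
    first <- ovt[, .SD[1L], by = pid]
    peaks$site_class[first$pid] <- first$family
  }
  peaks[, alu := grepl("Alu", site_class)]

  # region: exon when overlapping any spliced exon of the assigned gene
  splex <- iso[feature == "exon" & is_pre_rna == FALSE,
               .(chrom, start, end)]
  data.table::setkey(splex, chrom, start, end)
  pq <- peaks[, .(chrom, start, end, pid = .I)]
  data.table::setkey(pq, chrom, start, end)
  ove <- data.table::foverlaps(pq, splex, type = "any", nomatch = NULL)
  peaks[, region := "intron"]
  peaks$region[unique(ove$pid)] <- "exon"
  peaks[, summit := NULL]
  out <- peaks[, .(chrom, start, end, strand, k, lambda, p_value, q_value,
                   gene_id, site_class, region, alu)]
  data.table::setorder(out, chrom, start)
  data.table::setattr(out, "window_stats", attr_out)
  out[]
}
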