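# Isoform abundance estimation (compatibility EM) and the uniform null model.

#' Estimate isoform abundances by compatibility EM
#'
#' Each alignment's weight is distributed across the isoforms it is compatible
#' with (all aligned blocks exonic and contiguous in transcript coordinates),
#' proportionally to the current abundance density `alpha_i / length_i`; the
#' M-step re-estimates `alpha` as the total assigned weight. Pre-RNA isoforms
#' (add them with [augment_pre_rna()] first) absorb intronic alignments, which
#' are incompatible with any spliced isoform.
#'
#' @param alignments weighted alignment table.
#' @param isoforms exon table, typically pre-RNA augmented.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @return an `abundance_model`: list with `isoforms` (isoform_id, gene_id,
#'   chrom, strand, length, mass = expected fragment count) and
#'   `library_size` (total weighted alignments).
#' @export
estimate_abundances <- function(alignments, isoforms, max_iter = 100L,
                                tol = 1e-6) {
  aln <- data.table::as.data.table(alignments)
  chains <- isoform_chains(isoforms)
  iso_meta <- data.table::data.table(
    isoform_id = names(chains),
    gene_id = vapply(chains, `[[`, character(1), "gene_id"),
    chrom = vapply(chains, `[[`, character(1), "chrom"),
    strand = vapply(chains, `[[`, character(1), "strand"),
    length = vapply(chains, `[[`, numeric(1), "len"))
  lib <- sum(aln$weight)
  compat <- compatibility_pairs(aln, chains)
  if (nrow(compat) == 0L) {
    warnf("no alignment is compatible with any isoform; all-zero model")
    iso_meta[, mass := 0]
    return(structure(list(isoforms = iso_meta, library_size = lib),
                     class = "abundance_model"))
  }
  n_iso <- length(chains)
  iso_idx <- match(compat$isoform_id, iso_meta$isoform_id)
  w <- aln$weight[compat$aln_id]
  len <- iso_meta$length[iso_idx]
  aln_grp <- match(compat$aln_id, sort(unique(compat$aln_id)))
  alpha <- rep(lib / n_iso, n_iso)
  for (it in seq_len(max_iter)) {
    dens <- alpha[iso_idx] / len
    denom <- rowsum(dens, aln_grp, reorder = TRUE)[, 1L]
    gamma <- dens / denom[aln_grp]
    new_alpha <- rep(0, n_iso)
    acc <- rowsum(gamma * w, iso_idx)
    new_alpha[as.integer(rownames(acc))] <- acc[, 1L]
    delta <- max(abs(new_alpha - alpha) / (alpha + 1e-12))
    alpha <- new_alpha
    if (delta < tol) break
  }
  iso_meta[, mass := alpha]
  structure(list(isoforms = iso_meta, library_size = lib),
            class = "abundance_model")
}

#' @export
print.abundance_model <- function(x, ...) {
  cat(sprintf("abundance_model: %d isoforms, %.1f weighted fragments, %d expressed\n",
              nrow(x$isoforms), x$library_size, sum(x$isoforms$mass > 0)))
  invisible(x)
}

# (alignment, isoform) compatibility pairs.
# Compatible: every aligned block lies inside one exon and the blocks form a
# contiguous run in transcript coordinates. Single-block alignments (the vast
# majority) take a vectorised path; junction reads are checked per pair.
compatibility_pairs <- function(aln, chains) {
  if (nrow(aln) == 0L) {
    return(data.table::data.table(aln_id = integer(0),
                                  isoform_id = character(0)))
  }
  iso_tab <- data.table::data.table(
    isoform_id = names(chains),
    iso_strand = vapply(chains, `[[`, character(1), "strand"),
    chrom = vapply(chains, `[[`, character(1), "chrom"),
    start = vapply(chains, function(ch) min(ch$starts), integer(1)),
    end = vapply(chains, function(ch) max(ch$ends), integer(1)))
  data.table::setkey(iso_tab, chrom, start, end)
  bl_all <- decode_blocks(aln$blocks)
  ends <- bl_all[, .(end = max(end), n_blocks = .N), by = row]
  data.table::setorder(ends, row)
  spans <- data.table::data.table(
    aln_id = seq_len(nrow(aln)), chrom = aln$chrom, aln_strand = aln$strand,
    start = aln$pos, end = ends$end, n_blocks = ends$n_blocks)
  data.table::setkey(spans, chrom, start, end)
  ov <- data.table::foverlaps(spans, iso_tab, type = "any", nomatch = NULL)
  ov <- ov[aln_strand == iso_strand]
  if (nrow(ov) == 0L) {
    return(data.table::data.table(aln_id = integer(0),
                                  isoform_id = character(0)))
  }
  keep <- logical(nrow(ov))
  sb <- which(ov$n_blocks == 1L)
  if (length(sb)) {
    iso_f <- ov$isoform_id[sb]
    for (id in unique(iso_f)) {
      ch <- chains[[id]]
      ii <- sb[iso_f == id]
      t1 <- genome_to_tx(ch, ov$i.start[ii])
      t2 <- genome_to_tx(ch, ov$i.end[ii])
      keep[ii] <- !is.na(t1) & !is.na(t2) &
        abs(t2 - t1) == (ov$i.end[ii] - ov$i.start[ii])
    }
  }
  mb <- which(ov$n_blocks > 1L)
  if (length(mb)) {
    need <- unique(ov$aln_id[mb])
    blocks_by_aln <- split(bl_all[row %in% need], by = "row")
    for (r in mb) {
      ch <- chains[[ov$isoform_id[r]]]
      b <- blocks_by_aln[[as.character(ov$aln_id[r])]]
      t1 <- genome_to_tx(ch, b$start)
      t2 <- genome_to_tx(ch, b$end)
      if (anyNA(t1) || anyNA(t2)) next
      if (!all(abs(t2 - t1) == (b$end - b$start))) next
      ts <- sort(pmin(t1, t2)); te_ <- sort(pmax(t1, t2))
      if (any(ts[-1L] != te_[-length(te_)] + 1L)) next
      keep[r] <- TRUE
    }
  }
  unique(ov[keep, .(aln_id, isoform_id)])
}

#' Simulate reads uniformly along transcripts (the null model)
#'
#' Draws `n_reads` reads with per-isoform probability proportional to its
#' fragment mass, start positions uniform along the transcript, and projects
#' them through the exon chain to genomic coordinates (junction reads become
#' multi-block placements). Strand is the isoform strand; every null read is
#' uniquely placed (weight 1).
#'
#' @param model an `abundance_model`.
#' @param isoforms exon table matching the model (pre-RNA augmented).
#' @param n_reads number of reads to draw, typically the observed library's
#'   distinct read count.
#' @param seed RNG seed.
#' @param read_len simulated read length (default 36).
#' @return alignment table.
#' @export
simulate_null <- function(model, isoforms, n_reads, seed = 1L,
                          read_len = 36L) {
  stopifnot(inherits(model, "abundance_model"))
  mi <- model$isoforms
  if (all(mi$mass <= 0)) stopf("abundance model is all zero")
  chains <- isoform_chains(isoforms)
  chains <- chains[mi$isoform_id]
  with_seed(seed, {
    pick <- sample.int(nrow(mi), n_reads, replace = TRUE, prob = mi$mass)
    len <- mi$length[pick]
    al <- pmin(read_len, len)
    npos <- pmax(1L, len - al + 1L)
    tstart <- 1L + floor(runif(n_reads) * npos)
    g1 <- integer(n_reads); g2 <- integer(n_reads)
    for (i in unique(pick)) {
      sel <- which(pick == i)
      ch <- chains[[i]]
      g1[sel] <- tx_to_genome(ch, tstart[sel])
      g2[sel] <- tx_to_genome(ch, tstart[sel] + al[sel] - 1L)
    }
    lo <- pmin(g1, g2); hi <- pmax(g1, g2)
    single <- (hi - lo) == (al - 1L)
    blocks <- character(n_reads)
    blocks[single] <- sprintf("%d:%d", lo[single], al[single])
    for (r in which(!single)) {
      b <- tx_interval_to_blocks(chains[[pick[r]]], tstart[r],
                                 tstart[r] + al[r] - 1L)
      blocks[r] <- encode_blocks(b$start, b$end - b$start + 1L)
    }
    data.table::data.table(
      read_id = sprintf("n%08d", seq_len(n_reads)),
      chrom = mi$chrom[pick],
      strand = mi$strand[pick],
      pos = lo, aligned_len = as.integer(al), blocks = blocks,
      n_alignments = 1L, weight = 1)
  })
}

#' Read sequences at alignment positions
#'
#' Extracts the reference sequence under each alignment (concatenated across
#' blocks, reverse-complemented for minus-strand placements). Used to send
#' simulated null reads back through the aligner, so the null experiences the
#' same mappability constraints as the data.
#'
#' @param aln alignment table.
#' @param genome genome sequences.
#' @return data.table with `read_id` and `seq`.
#' @export
alignment_seqs <- function(aln, genome) {
  dt <- data.table::as.data.table(aln)
  bl <- decode_blocks(dt$blocks)
  seqs <- character(nrow(dt))
  for (cn in unique(dt$chrom)) {
    s <- chrom_string(genome, cn)
    rows <- which(dt$chrom == cn)
    b <- bl[bl$row %in% rows]
    part <- substring(s, b$start, b$end)
    seqs[rows] <- vapply(split(part, b$row), paste, character(1),
                         collapse = "")[as.character(rows)]
  }
  minus <- dt$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  data.table::data.table(read_id = dt$read_id, seq = seqs)
}

#' Simulate the null library and map it back through the aligner
#'
#' Draws uniform reads from the abundance model ([simulate_null()]), extracts
#' their sequences and re-aligns them with [align_prefix_iterative()], then
#' applies the positional duplicate cap -- the same processing the CLIP
#' library received, so family-level and consensus-position comparisons are
#' controlled for mappability and duplicate saturation.
#'
#' @param model an `abundance_model`.
#' @param isoforms pre-RNA augmented exon table.
#' @param genome genome sequences.
#' @param index an `aligner_index` (rebuilt if `NULL`).
#' @param n_reads library size to simulate.
#' @param seed RNG seed.
#' @param read_len read length.
#' @param cap positional duplicate cap (default 2).
#' @return weighted, capped alignment table.
#' @export
simulate_null_mapped <- function(model, isoforms, genome, index = NULL,
                                 n_reads, seed = 1L, read_len = 36L,
                                 cap = 2L) {
  ideal <- simulate_null(model, isoforms, n_reads, seed = seed,
                         read_len = read_len)
  reads <- alignment_seqs(ideal, genome)
  if (is.null(index)) index <- build_aligner_index(genome, isoforms)
  aln <- align_prefix_iterative(reads, index, seed = seed)
  cap_positional_duplicates(aln, cap = cap)
}
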