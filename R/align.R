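# Adapter-ignorant iterative prefix alignment.
#
# The contract: align the first min_prefix nucleotides of each read; a unique
# hit is returned at once; ambiguous reads are retried with the prefix grown
# one base at a time; when a read that aligned at length L-1 loses all hits at
# length L (presumably the adapter began), its alignments from L-1 are
# returned. Matching is exact (the generator's reads copy the reference
# verbatim); splice awareness comes from indexing spliced transcript sequences
# and projecting hits back through the exon chain.

#' Build an exact-match aligner index
#'
#' Indexes every `min_prefix`-mer of the genome (both strands) and of the
#' spliced transcript sequences. Transcript hits are projected to genomic
#' coordinates through the exon chain; hits identical to a genomic hit are
#' deduplicated.
#'
#' @param genome named [Biostrings::DNAStringSet] or character vector.
#' @param isoforms exon table (spliced isoforms; pre-RNA rows are ignored,
#'   they duplicate the genome).
#' @param min_prefix seed length (default 20).
#' @return an `aligner_index`.
#' @export
build_aligner_index <- function(genome, isoforms = NULL, min_prefix = 20L) {
  cl <- chrom_lengths(genome)
  refs <- list(); meta <- list()
  for (cn in names(cl)) {
    s <- chrom_string(genome, cn)
    refs[[length(refs) + 1L]] <- s
    meta[[length(meta) + 1L]] <- list(type = "g", chrom = cn, strand = "+",
                                      len = cl[[cn]])
    refs[[length(refs) + 1L]] <- revcomp(s)
    meta[[length(meta) + 1L]] <- list(type = "g", chrom = cn, strand = "-",
                                      len = cl[[cn]])
  }
  chains <- list()
  if (!is.null(isoforms)) {
    iso <- data.table::as.data.table(isoforms)[feature == "exon" &
                                                 is_pre_rna == FALSE]
    if (nrow(iso)) {
      chains <- isoform_chains(iso)
      for (id in names(chains)) {
        refs[[length(refs) + 1L]] <- transcript_seq(genome, chains[[id]])
        meta[[length(meta) + 1L]] <- list(type = "t", isoform = id,
                                          len = chains[[id]]$len)
      }
    }
  }
  refs <- unlist(refs)
  k <- as.integer(min_prefix)
  kt <- list()
  for (i in seq_along(refs)) {
    codes <- encode_kmers(refs[i], k)
    if (is.null(codes)) next
    ok <- which(!is.na(codes))
    kt[[length(kt) + 1L]] <- data.table::data.table(
      kmer = codes[ok], ref_i = i, pos = ok)
  }
  kt <- data.table::rbindlist(kt)
  data.table::setkey(kt, kmer)
  # flattened per-base characters for O(1) extension lookups
  flat <- unlist(strsplit(refs, "", fixed = TRUE), use.names = FALSE)
  offs <- c(0L, cumsum(nchar(refs)))
  structure(list(kmers = kt, refs = refs, meta = meta, chains = chains,
                 flat = flat, offs = offs, min_prefix = k,
                 chrom_lengths = cl),
            class = "aligner_index")
}

#' Align reads by iterative prefix extension
#'
#' Implements the adapter-ignorant strategy described above. Reads shorter
#' than `min_prefix` are skipped (counted in the `n_short` attribute); reads
#' with no hit at `min_prefix` are discarded (`n_unaligned`). Reads with more
#' than `max_alignments` surviving placements are downsampled to
#' `max_alignments` with the fixed seed, and count `1/max_alignments` each.
#'
#' @param reads data.table with `read_id` and `seq` (or a named character
#'   vector of sequences).
#' @param index an `aligner_index` from [build_aligner_index()].
#' @param min_prefix seed length; must equal the index's.
#' @param max_alignments per-read placement cap (default 20).
#' @param seed RNG seed for cap downsampling.
#' @return alignment table with `read_id`, `chrom`, `strand`, `pos`,
#'   `aligned_len`, `blocks`, `n_alignments`, `weight`.
#' @export
align_prefix_iterative <- function(reads, index, min_prefix = index$min_prefix,
                                   max_alignments = 20L, seed = 1L) {
  stopifnot(inherits(index, "aligner_index"))
  if (min_prefix != index$min_prefix)
    stopf("index was built for min_prefix = %d", index$min_prefix)
  if (!is.data.frame(reads))
    reads <- data.table::data.table(read_id = names(reads), seq = unname(reads))
  reads <- data.table::as.data.table(reads)
  rlen <- nchar(reads$seq)
  short <- rlen < min_prefix
  n_short <- sum(short)
  rd <- reads[!short]
  rlen <- rlen[!short]
  empty <- data.table::data.table(
    read_id = character(0), chrom = character(0), strand = character(0),
    pos = integer(0), aligned_len = integer(0), blocks = character(0),
    n_alignments = integer(0), weight = numeric(0))
  if (nrow(rd) == 0L) {
    data.table::setattr(empty, "n_short", n_short)
    data.table::setattr(empty, "n_unaligned", 0L)
    return(empty)
  }

  # seed candidates from the k-mer table
  qk <- encode_words(substr(rd$seq, 1L, min_prefix), min_prefix)
  q <- data.table::data.table(read_i = seq_len(nrow(rd)), kmer = qk)
  q <- q[!is.na(kmer)]
  cand <- index$kmers[q, on = "kmer", nomatch = NULL,
                      .(read_i, ref_i, pos)]
  aligned_reads <- unique(cand$read_i)
  n_unaligned <- nrow(rd) - length(aligned_reads)
  if (nrow(cand) == 0L) {
    data.table::setattr(empty, "n_short", n_short)
    data.table::setattr(empty, "n_unaligned", n_unaligned)
    return(empty)
  }

  # extend every candidate to its maximal exact match length
  read_flat <- unlist(strsplit(rd$seq, "", fixed = TRUE), use.names = FALSE)
  read_offs <- c(0L, cumsum(rlen))
  ref_len <- nchar(index$refs)
  m <- rep(as.integer(min_prefix), nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  maxL <- max(rlen)
  if (maxL > min_prefix) {
    for (L in seq(min_prefix + 1L, maxL, by = 1L)) {
      cur <- which(alive)
      if (!length(cur)) break
      can_ext <- rlen[cand$read_i[cur]] >= L &
        (cand$pos[cur] + L - 1L) <= ref_len[cand$ref_i[cur]]
      alive[cur[!can_ext]] <- FALSE
      act <- cur[can_ext]
      if (!length(act)) break
      rc <- read_flat[read_offs[cand$read_i[act]] + L]
      gc_ <- index$flat[index$offs[cand$ref_i[act]] + cand$pos[act] + L - 1L]
      ok <- rc == gc_
      m[act[ok]] <- L
      alive[act[!ok]] <- FALSE
    }
  }
  cand[, m := m]

  # genomic key of the first read base, for deduplicating genome vs transcript
  cand <- annotate_candidates(cand, index)
  data.table::setorder(cand, read_i, chrom, strand, key_, -m, ref_type)
  cand <- cand[, .SD[1L], by = .(read_i, chrom, strand, key_)]

  # the iterative-prefix decision per read
  dec <- cand[, {
    mm <- sort(m, decreasing = TRUE)
    if (.N == 1L) {
      list(idx = .I[1L], alen = as.integer(min_prefix))
    } else if (sum(m == mm[1L]) == 1L) {
      list(idx = .I[which.max(m)], alen = min(mm[2L] + 1L, mm[1L]))
    } else {
      list(idx = .I[m == mm[1L]], alen = mm[1L])
    }
  }, by = read_i]
  surv <- cand[dec$idx]
  surv[, aligned_len := dec$alen]

  # project survivors to genomic blocks at their aligned length
  out <- project_survivors(surv, rd, index)
  # final genomic dedupe (a transcript hit can coincide with a genome hit)
  out <- unique(out, by = c("read_id", "chrom", "strand", "blocks"))
  out[, n_alignments := .N, by = read_id]
  over <- out[n_alignments > max_alignments, unique(read_id)]
  if (length(over)) {
    data.table::setorder(out, read_id, chrom, pos, strand)
    keep <- with_seed(seed, {
      out[, if (.N <= max_alignments) .I else sort(sample(.I, max_alignments)),
          by = read_id]$V1
    })
    out <- out[sort(keep)]
    out[read_id %in% over, n_alignments := as.integer(max_alignments)]
  }
  out[, weight := 1 / n_alignments]
  data.table::setorder(out, read_id, chrom, pos)
  out <- out[, .(read_id, chrom, strand, pos, aligned_len, blocks,
                 n_alignments, weight)]
  data.table::setattr(out, "n_short", n_short)
  data.table::setattr(out, "n_unaligned", n_unaligned)
  out[]
}

# attach chrom/strand and the genomic coordinate of the read's first base
annotate_candidates <- function(cand, index) {
  type <- vapply(index$meta, `[[`, character(1), "type")
  cand[, ref_type := type[ref_i]]
  cand[, chrom := NA_character_]
  cand[, strand := NA_character_]
  cand[, key_ := NA_integer_]
  gsel <- which(cand$ref_type == "g")
  if (length(gsel)) {
    mchrom <- vapply(index$meta, function(m) m$chrom %||% NA_character_,
                     character(1))
    mstrand <- vapply(index$meta, function(m) m$strand %||% NA_character_,
                      character(1))
    mlen <- vapply(index$meta, function(m) m$len %||% NA_integer_, numeric(1))
    cand$chrom[gsel] <- mchrom[cand$ref_i[gsel]]
    cand$strand[gsel] <- mstrand[cand$ref_i[gsel]]
    plus <- cand$strand[gsel] == "+"
    cand$key_[gsel] <- ifelse(plus, cand$pos[gsel],
                              as.integer(mlen[cand$ref_i[gsel]]) -
                                cand$pos[gsel] + 1L)
  }
  tsel <- which(cand$ref_type == "t")
  if (length(tsel)) {
    miso <- vapply(index$meta, function(m) m$isoform %||% NA_character_,
                   character(1))
    iso <- miso[cand$ref_i[tsel]]
    for (id in unique(iso)) {
      ch <- index$chains[[id]]
      ii <- tsel[iso == id]
      cand$chrom[ii] <- ch$chrom
      cand$strand[ii] <- ch$strand
      cand$key_[ii] <- tx_to_genome(ch, cand$pos[ii])
    }
  }
  cand
}

# genomic blocks for surviving candidates at their aligned length
project_survivors <- function(surv, rd, index) {
  mlen <- vapply(index$meta, function(m) m$len %||% NA_integer_, numeric(1))
  n <- nrow(surv)
  chromv <- surv$chrom; strandv <- surv$strand
  posv <- integer(n); blocksv <- character(n)
  g <- which(surv$ref_type == "g")
  if (length(g)) {
    plus <- surv$strand[g] == "+"
    al <- surv$aligned_len[g]
    posv[g] <- ifelse(plus, surv$pos[g],
                      as.integer(mlen[surv$ref_i[g]]) -
                        (surv$pos[g] + al - 1L) + 1L)
    blocksv[g] <- sprintf("%d:%d", posv[g], al)
  }
  t <- which(surv$ref_type == "t")
  if (length(t)) {
    miso <- vapply(index$meta, function(m) m$isoform %||% NA_character_,
                   character(1))
    for (r in t) {
      ch <- index$chains[[miso[surv$ref_i[r]]]]
      b <- tx_interval_to_blocks(ch, surv$pos[r],
                                 surv$pos[r] + surv$aligned_len[r] - 1L)
      posv[r] <- b$start[1L]
      blocksv[r] <- encode_blocks(b$start, b$end - b$start + 1L)
    }
  }
  data.table::data.table(
    read_id = rd$read_id[surv$read_i], chrom = chromv, strand = strandv,
    pos = posv, aligned_len = surv$aligned_len, blocks = blocksv)
}

#' Cap alignments per chromosomal position
#'
#' Retains at most `cap` alignments per (chrom, pos, strand), breaking ties by
#' lexicographic `read_id`, which removes the bulk of PCR duplicates while
#' keeping redundancy expected in enriched clusters.
#'
#' @param aln alignment table.
#' @param cap maximum alignments per position (default 2).
#' @return filtered alignment table.
#' @export
cap_positional_duplicates <- function(aln, cap = 2L) {
  dt <- data.table::as.data.table(aln)
  data.table::setorder(dt, chrom, pos, strand, read_id)
  dt[, rid := seq_len(.N), by = .(chrom, pos, strand)]
  out <- dt[rid <= cap]
  out[, rid := NULL]
  out[]
}

#' Minimum-depth dataset filter
#'
#' Datasets with fewer than `min_reads` distinct aligned reads are flagged as
#' unreliable.
#'
#' @param aln alignment table.
#' @param min_reads threshold (default 200000).
#' @return list with `pass` (logical) and `n_reads` (distinct aligned reads).
#' @export
filter_dataset_depth <- function(aln, min_reads = 200000L) {
  n <- length(unique(aln$read_id))
  list(pass = n >= min_reads, n_reads = n)
}
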