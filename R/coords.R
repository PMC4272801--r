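# Exon-chain coordinate projection.
#
# Transcript coordinates are 1-based along the mature (spliced) RNA in its
# 5'->3' direction; genomic coordinates are 1-based closed. For a minus-strand
# isoform, transcript position 1 is the rightmost genomic base of the last
# exon.

# exon chains as a named list for fast repeated projection
# isoforms: exon table (see read_gtf); returns list keyed by isoform_id with
# starts, ends (ascending), strand, chrom, len, gene_id
isoform_chains <- function(isoforms) {
  ex <- data.table::as.data.table(isoforms)[feature == "exon"]
  data.table::setorder(ex, isoform_id, start)
  sp <- split(ex, by = "isoform_id", keep.by = TRUE)
  lapply(sp, function(d) {
    list(isoform_id = d$isoform_id[1], gene_id = d$gene_id[1],
         chrom = d$chrom[1], strand = d$strand[1],
         starts = as.integer(d$start), ends = as.integer(d$end),
         len = as.integer(sum(d$end - d$start + 1)))
  })
}

#' Project transcript positions to genomic positions
#'
#' @param chain an exon chain as produced by the internal `isoform_chains()`:
#'   a list with `starts`, `ends` (ascending genomic exon intervals) and
#'   `strand`.
#' @param tpos integer vector of transcript positions (1-based, 5'->3').
#' @return integer vector of genomic positions; `NA` outside the transcript.
#' @export
tx_to_genome <- function(chain, tpos) {
  lens <- chain$ends - chain$starts + 1L
  txlen <- sum(lens)
  out <- rep(NA_integer_, length(tpos))
  okp <- which(!is.na(tpos) & tpos >= 1L & tpos <= txlen)
  if (!length(okp)) return(out)
  tp <- tpos[okp]
  if (chain$strand == "+") {
    cum0 <- c(0L, cumsum(lens))
    idx <- findInterval(tp - 1L, cum0)
    out[okp] <- chain$starts[idx] + (tp - cum0[idx] - 1L)
  } else {
    rl <- rev(lens)
    cum0 <- c(0L, cumsum(rl))
    idxr <- findInterval(tp - 1L, cum0)
    i <- length(lens) - idxr + 1L
    out[okp] <- chain$ends[i] - (tp - cum0[idxr] - 1L)
  }
  out
}

#' Project genomic positions to transcript positions
#'
#' @inheritParams tx_to_genome
#' @param gpos integer vector of genomic positions.
#' @return integer vector of transcript positions; `NA` for non-exonic bases.
#' @export
genome_to_tx <- function(chain, gpos) {
  lens <- chain$ends - chain$starts + 1L
  out <- rep(NA_integer_, length(gpos))
  idx <- findInterval(gpos, chain$starts)
  ok <- which(idx >= 1L & !is.na(gpos))
  ok <- ok[gpos[ok] <= chain$ends[idx[ok]]]
  if (!length(ok)) return(out)
  if (chain$strand == "+") {
    cum0 <- c(0L, cumsum(lens))
    out[ok] <- cum0[idx[ok]] + (gpos[ok] - chain$starts[idx[ok]] + 1L)
  } else {
    cum0 <- c(0L, cumsum(rev(lens)))
    j <- length(lens) - idx[ok] + 1L
    out[ok] <- cum0[j] + (chain$ends[idx[ok]] - gpos[ok] + 1L)
  }
  out
}

#' Project a transcript interval to genomic blocks
#'
#' @inheritParams tx_to_genome
#' @param t1,t2 transcript interval bounds (1-based, `t1 <= t2`).
#' @return data.table with `start`, `end` genomic blocks in ascending order.
#' @export
tx_interval_to_blocks <- function(chain, t1, t2) {
  stopifnot(t1 >= 1L, t2 >= t1)
  lens <- chain$ends - chain$starts + 1L
  n <- length(lens)
  if (chain$strand == "+") {
    cum0 <- c(0L, cumsum(lens))
    gs <- ge <- integer(0)
    for (i in seq_len(n)) {
      a <- max(t1, cum0[i] + 1L); b <- min(t2, cum0[i + 1L])
      if (a <= b) {
        gs <- c(gs, chain$starts[i] + (a - cum0[i] - 1L))
        ge <- c(ge, chain$starts[i] + (b - cum0[i] - 1L))
      }
    }
  } else {
    cum0 <- c(0L, cumsum(rev(lens)))
    gs <- ge <- integer(0)
    for (j in seq_len(n)) {
      a <- max(t1, cum0[j] + 1L); b <- min(t2, cum0[j + 1L])
      if (a <= b) {
        i <- n - j + 1L
        ge <- c(ge, chain$ends[i] - (a - cum0[j] - 1L))
        gs <- c(gs, chain$ends[i] - (b - cum0[j] - 1L))
      }
    }
  }
  d <- data.table::data.table(start = as.integer(gs), end = as.integer(ge))
  data.table::setorder(d, start)
  d[]
}

#' Spliced transcript sequence from a genome
#'
#' @param genome a named [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences.
#' @inheritParams tx_to_genome
#' @return single character string, the transcript sequence 5'->3'.
#' @export
transcript_seq <- function(genome, chain) {
  seqs <- chrom_string(genome, chain$chrom)
  parts <- substring(seqs, chain$starts, chain$ends)
  s <- paste(parts, collapse = "")
  if (chain$strand == "-") s <- revcomp(s)
  s
}

# fetch one chromosome as a plain character string
chrom_string <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet")) as.character(genome[[chrom]])
  else genome[[chrom]]
}

# chromosome lengths as a named integer vector
chrom_lengths <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(genome, nchar, integer(1))
  }
}
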