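# Weighted alignments and their SAM-like text representation.
#
# Internal alignment tables have one row per placement:
#   read_id, chrom, strand, pos (1-based leftmost aligned base),
#   aligned_len (aligned read bases), blocks ("start:len,start:len" genomic
#   segments, ascending), n_alignments (placements of the read, <= cap),
#   weight (= 1/n_alignments).

# build an alignment table from components, filling derived fields
make_alignments <- function(read_id, chrom, strand, blocks, n_alignments = 1L) {
  bl <- decode_blocks(blocks)
  lens <- bl[, .(aligned_len = sum(end - start + 1L), pos = min(start)),
             by = row]
  data.table::setorder(lens, row)
  data.table::data.table(
    read_id = read_id, chrom = chrom, strand = strand,
    pos = lens$pos,
    aligned_len = lens$aligned_len,
    blocks = blocks,
    n_alignments = as.integer(n_alignments),
    weight = 1 / as.integer(n_alignments)
  )
}

# expand alignments to one row per genomic block;
# returns data.table(aln_id, read_id, chrom, strand, start, end, weight)
alignment_blocks <- function(aln) {
  dt <- data.table::as.data.table(aln)
  bl <- decode_blocks(dt$blocks)
  out <- data.table::data.table(
    aln_id = bl$row, read_id = dt$read_id[bl$row],
    chrom = dt$chrom[bl$row], strand = dt$strand[bl$row],
    start = bl$start, end = bl$end, weight = dt$weight[bl$row])
  out
}

cigar_from_blocks <- function(blocks) {
  vapply(blocks, function(b) {
    d <- decode_blocks(b)
    parts <- sprintf("%dM", d$end - d$start + 1L)
    gaps <- if (nrow(d) > 1) sprintf("%dN", d$start[-1] - d$end[-nrow(d)] - 1L)
            else character(0)
    paste(c(rbind(parts, c(gaps, ""))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

blocks_from_cigar <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  vapply(seq_along(cigar), function(i) {
    len <- as.integer(sub("[A-Z=]", "", ops[[i]]))
    op <- sub("[0-9]+", "", ops[[i]])
    if (any(!op %in% c("M", "N", "S", "=", "X")))
      stopf("unsupported CIGAR op '%s'", op[!op %in% c("M", "N", "S", "=", "X")][1])
    p <- pos[i]
    starts <- integer(0); lens <- integer(0)
    for (j in seq_along(op)) {
      if (op[j] %in% c("M", "=", "X")) {
        starts <- c(starts, p); lens <- c(lens, len[j]); p <- p + len[j]
      } else if (op[j] == "N") p <- p + len[j]
      # S consumes only the read; ignored for genomic blocks
    }
    encode_blocks(starts, lens)
  }, character(1))
}

#' Write weighted alignments as SAM-like text
#'
#' Emits headerless SAM records (FLAG 16 encodes the minus strand, gapped
#' placements use M/N CIGARs) with the `NH:i:` alignment-count tag.
#'
#' @param aln alignment table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  dt <- data.table::as.data.table(aln)
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\tNH:i:%d",
                   dt$read_id, ifelse(dt$strand == "-", 16L, 0L),
                   dt$chrom, dt$pos, cigar_from_blocks(dt$blocks),
                   dt$n_alignments)
  writeLines(lines, path)
  invisible(path)
}

#' Read weighted alignments from SAM-like text
#'
#' Unmapped records (FLAG 0x4 or RNAME `*`) are skipped and counted in the
#' `n_unmapped` attribute. Records missing the `NH` tag get `n_alignments`
#' inferred from the multiplicity of their `read_id` in the file. Reads with
#' more than `max_alignments` placements are downsampled to `max_alignments`
#' with a fixed seed.
#'
#' @param path SAM-like file (headers tolerated).
#' @param max_alignments per-read placement cap (default 20).
#' @param seed RNG seed for the deterministic downsampling.
#' @return alignment table (see [write_alignments()] for fields).
#' @export
read_alignments <- function(path, max_alignments = 20L, seed = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines)) {
    out <- data.table::data.table(
      read_id = character(0), chrom = character(0), strand = character(0),
      pos = integer(0), aligned_len = integer(0), blocks = character(0),
      n_alignments = integer(0), weight = numeric(0))
    data.table::setattr(out, "n_unmapped", 0L)
    return(out)
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  flag <- as.integer(f[[2]])
  unmapped <- bitwAnd(flag, 4L) > 0L | f[[3]] == "*"
  n_unmapped <- sum(unmapped)
  dt <- data.table::data.table(
    read_id = f[[1]][!unmapped], flag = flag[!unmapped],
    chrom = f[[3]][!unmapped], pos = as.integer(f[[4]][!unmapped]),
    cigar = f[[6]][!unmapped],
    tags = do.call(paste, c(lapply(f[-(1:11)], function(x) x[!unmapped] %||% ""),
                            sep = "\t"))
  )
  nh <- suppressWarnings(as.integer(
    sub(".*NH:i:([0-9]+).*", "\\1", dt$tags)))
  nh[!grepl("NH:i:", dt$tags)] <- NA_integer_
  dt[, n_alignments := nh]
  dt[is.na(n_alignments), n_alignments := .N, by = read_id]
  dt[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  dt[, blocks := blocks_from_cigar(cigar, pos)]
  bl <- decode_blocks(dt$blocks)
  al <- bl[, .(aligned_len = sum(end - start + 1L)), by = row]
  dt[al$row, aligned_len := al$aligned_len]
  # enforce the placement cap by seeded downsampling
  over <- dt[, .N, by = read_id][N > max_alignments]
  if (nrow(over)) {
    data.table::setorder(dt, read_id, chrom, pos, strand)
    keep <- with_seed(seed, {
      dt[, if (.N <= max_alignments) .I else sort(sample(.I, max_alignments)),
         by = read_id]$V1
    })
    dt <- dt[sort(keep)]
    dt[read_id %in% over$read_id, n_alignments := as.integer(max_alignments)]
  }
  dt[, weight := 1 / n_alignments]
  out <- dt[, .(read_id, chrom, strand, pos, aligned_len, blocks,
                n_alignments, weight)]
  data.table::setattr(out, "n_unmapped", n_unmapped)
  out[]
}
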