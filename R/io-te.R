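# TE instance annotation in a RepeatMasker .out-like dialect.
#
# Columns (whitespace separated, after the 3 header lines):
#   SW div del ins chrom begin end (left) strand repName class/family
#   repStart repEnd repLeft ID
# Plus-strand rows carry consensus coordinates as repStart/repEnd with the
# remaining consensus length "(n)" in repLeft; minus-strand rows ("C") swap the
# columns: "(n)" occupies repStart, repEnd holds the consensus end, repLeft the
# consensus start. read_te_annotation() undoes the swap so that
# cons_start < cons_end on the consensus in either orientation.

#' Read TE instances from a RepeatMasker-style table
#'
#' Minus-strand consensus coordinates are normalised (the RepeatMasker column
#' swap is undone). Records whose consensus span exceeds the declared (or
#' supplied) consensus length are rejected with a warning, as are records whose
#' genomic and consensus span lengths disagree by more than `indel_tol`
#' (relative); the realised maximum relative disagreement is recorded in the
#' `indel_tolerance` attribute.
#'
#' @param path annotation file.
#' @param cons_lengths optional named vector of consensus lengths per family;
#'   when given, overrides the lengths implied by the records and is used for
#'   validation.
#' @param indel_tol maximum tolerated relative difference between genomic span
#'   and consensus span (default 0.2).
#' @return data.table with columns chrom, start, end (1-based closed), strand,
#'   family, subfamily, cons_start, cons_end, cons_length.
#' @export
read_te_annotation <- function(path, cons_lengths = NULL, indel_tol = 0.2) {
  lines <- readLines(path)
  if (length(lines) >= 1 && grepl("\\bSW\\b|score", lines[1]))
    lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("no TE records in %s", path)
  f <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(f)
  if (any(nf < 14)) stopf("malformed TE record at line %d", which(nf < 14)[1])
  g <- function(i) vapply(f, `[[`, character(1), i)
  paren <- function(x) suppressWarnings(as.integer(gsub("[()]", "", x)))
  strand <- ifelse(g(9) %in% c("C", "-"), "-", "+")
  r12 <- g(12); r13 <- g(13); r14 <- g(14)
  cons_start <- ifelse(strand == "+", suppressWarnings(as.integer(r12)),
                       paren(r14))
  cons_end <- suppressWarnings(as.integer(r13))
  left <- ifelse(strand == "+", paren(r14), paren(r12))
  dt <- data.table::data.table(
    chrom = g(5),
    start = as.integer(g(6)), end = as.integer(g(7)),
    strand = strand,
    subfamily = g(10), family = g(11),
    cons_start = as.integer(cons_start), cons_end = as.integer(cons_end),
    cons_length = as.integer(cons_end + left)
  )
  if (!is.null(cons_lengths)) {
    known <- dt$family %in% names(cons_lengths)
    dt[known, cons_length := as.integer(cons_lengths[family])]
  }
  bad <- dt$cons_start < 1L | dt$cons_end < dt$cons_start |
    dt$cons_end > dt$cons_length | dt$start >= dt$end + 1L & FALSE |
    dt$start > dt$end
  if (any(bad)) {
    warnf("rejected %d TE record(s) with invalid consensus span", sum(bad))
    dt <- dt[!bad]
  }
  gl <- dt$end - dt$start + 1L
  cl <- dt$cons_end - dt$cons_start + 1L
  rel <- abs(gl - cl) / pmax(gl, cl)
  indel <- rel > indel_tol
  if (any(indel)) {
    warnf("rejected %d TE record(s) beyond the indel tolerance %.2f",
          sum(indel), indel_tol)
    dt <- dt[!indel]
    rel <- rel[!indel]
  }
  data.table::setattr(dt, "indel_tolerance",
                      if (length(rel)) max(rel) else 0)
  data.table::setorder(dt, chrom, start)
  dt[]
}

#' Write TE instances in the RepeatMasker-style dialect
#'
#' Inverse of [read_te_annotation()]; minus-strand rows use the "C" strand
#' code and the swapped consensus columns.
#'
#' @param te TE instance table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_te_annotation <- function(te, path) {
  dt <- data.table::as.data.table(te)
  left <- dt$cons_length - dt$cons_end
  plus <- dt$strand == "+"
  r12 <- ifelse(plus, as.character(dt$cons_start), sprintf("(%d)", left))
  r13 <- as.character(dt$cons_end)
  r14 <- ifelse(plus, sprintf("(%d)", left), as.character(dt$cons_start))
  body <- sprintf("%5d %4.1f %4.1f %4.1f %s %d %d (0) %s %s %s %s %s %s %d",
                  1000L, 0, 0, 0, dt$chrom, dt$start, dt$end,
                  ifelse(plus, "+", "C"), dt$subfamily, dt$family,
                  r12, r13, r14, seq_len(nrow(dt)))
  header <- c(
    "   SW  perc perc perc  query    position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  writeLines(c(header, body), path)
  invisible(path)
}
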