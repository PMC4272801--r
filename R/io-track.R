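# Per-base score tracks (e.g. conservation scores) backed by bedGraph files.
#
# A score_track is a list of per-chromosome numeric vectors in which NA marks
# positions absent from the track (distinct from score 0).

#' Build a score track from per-chromosome vectors
#'
#' @param scores named list of numeric vectors (one per chromosome, full
#'   chromosome length, `NA` = missing).
#' @return a `score_track` object.
#' @export
score_track <- function(scores) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  structure(list(scores = scores), class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  n <- sum(vapply(x$scores, function(v) sum(!is.na(v)), numeric(1)))
  cat(sprintf("score_track: %d chromosomes, %d scored bases\n",
              length(x$scores), n))
  invisible(x)
}

#' Read a bedGraph file into a score track
#'
#' bedGraph intervals are 0-based half-open on disk and converted to the
#' package's 1-based closed convention.
#'
#' @param path bedGraph file.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return a `score_track`.
#' @export
read_score_track <- function(path, chrom_lengths) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start0", "end0", "score"))
  scores <- lapply(names(chrom_lengths), function(cn) {
    v <- rep(NA_real_, chrom_lengths[[cn]])
    d <- dt[chrom == cn]
    if (nrow(d)) {
      if (any(d$end0 > chrom_lengths[[cn]]))
        stopf("track interval beyond end of %s", cn)
      idx <- sequence(d$end0 - d$start0, from = d$start0 + 1L)
      v[idx] <- rep(d$score, d$end0 - d$start0)
    }
    v
  })
  names(scores) <- names(chrom_lengths)
  score_track(scores)
}

#' Write a score track as bedGraph
#'
#' Runs of equal consecutive scores are merged into single intervals.
#'
#' @param track a `score_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  out <- lapply(names(track$scores), function(cn) {
    v <- track$scores[[cn]]
    ok <- !is.na(v)
    if (!any(ok)) return(NULL)
    idx <- which(ok)
    brk <- c(TRUE, diff(idx) != 1L | v[idx][-1] != v[idx][-length(idx)])
    grp <- cumsum(brk)
    data.table::data.table(
      chrom = cn,
      start0 = tapply(idx, grp, min) - 1L,
      end0 = as.integer(tapply(idx, grp, max)),
      score = as.numeric(tapply(v[idx], grp, `[`, 1L)))
  })
  dt <- data.table::rbindlist(out)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Look up track scores at positions
#'
#' @param track a `score_track`.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 1-based positions.
#' @return numeric vector of scores (`NA` where missing).
#' @export
track_values <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_real_, n)
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    v <- track$scores[[cn]]
    if (is.null(v)) next
    p <- pos[i]
    ok <- p >= 1L & p <= length(v)
    out[i[ok]] <- v[p[ok]]
  }
  out
}
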