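# Projection of alignment coverage onto TE consensus coordinates and
# extraction of TE-specific motifs (TESMs).

# map aligned bases inside matching instances to consensus positions.
# orientation filters reads by strand relative to the instance strand.
# Returns data.table(aln_id, chrom, gpos, read_strand, cons_pos, weight).
# Instances whose genomic span differs from the consensus span (indels) are
# projected by linear interpolation.
consensus_base_map <- function(aln, te, family, orientation) {
  te <- data.table::as.data.table(te)
  .fam <- family
  inst <- te[te$family == .fam]
  if (nrow(inst) == 0L) stopf("family '%s' has no instances", family)
  bl <- alignment_blocks(aln)
  if (nrow(bl) == 0L) {
    return(data.table::data.table(aln_id = integer(0), chrom = character(0),
                                  gpos = integer(0), read_strand = character(0),
                                  cons_pos = integer(0), weight = numeric(0)))
  }
  inst[, inst_i := .I]
  data.table::setkey(inst, chrom, start, end)
  data.table::setkey(bl, chrom, start, end)
  ov <- data.table::foverlaps(bl, inst, type = "any", nomatch = NULL)
  want <- if (orientation == "sense") ov$i.strand == ov$strand
          else ov$i.strand != ov$strand
  ov <- ov[want]
  if (nrow(ov) == 0L) {
    return(data.table::data.table(aln_id = integer(0), chrom = character(0),
                                  gpos = integer(0), read_strand = character(0),
                                  cons_pos = integer(0), weight = numeric(0)))
  }
  s <- pmax(ov$i.start, ov$start)
  e <- pmin(ov$i.end, ov$end)
  lens <- e - s + 1L
  gpos <- sequence(lens, from = s)
  rep_i <- rep(seq_len(nrow(ov)), lens)
  glen <- ov$end - ov$start
  scale <- (ov$cons_end - ov$cons_start) / pmax(1L, glen)
  off <- gpos - ov$start[rep_i]
  cons <- ifelse(ov$strand[rep_i] == "+",
                 ov$cons_start[rep_i] + round(off * scale[rep_i]),
                 ov$cons_end[rep_i] - round(off * scale[rep_i]))
  cons <- pmin(pmax(as.integer(cons), 1L), ov$cons_length[rep_i])
  data.table::data.table(
    aln_id = ov$aln_id[rep_i], chrom = ov$chrom[rep_i], gpos = gpos,
    read_strand = ov$i.strand[rep_i], cons_pos = cons,
    weight = ov$weight[rep_i])
}

#' Consensus-coordinate coverage profile for one TE family and orientation
#'
#' Projects every aligned base inside an instance of the family onto the
#' family consensus (via the instance's recorded consensus span, linearly
#' interpolated when the copy carries indels) and accumulates CLIP and null
#' weights per consensus position. The normalised ratio is
#' `(clip_cov + eps) / (null_cov + eps) * (null_total / clip_total)`.
#'
#' @param clip,null weighted alignment tables.
#' @param te_instances TE instance table.
#' @param family TE family name.
#' @param orientation `"sense"` or `"antisense"` (read strand vs TE strand).
#' @param eps smoothing constant for zero-coverage positions (default 0.5).
#' @param clip_total,null_total library sizes; default to the summed weights
#'   of the full alignment tables.
#' @return a `consensus_profile`: list with `family`, `orientation`,
#'   `cons_length`, `clip_cov`, `null_cov`, `norm_ratio`, `clip_total`,
#'   `null_total`.
#' @export
build_consensus_profile <- function(clip, null, te_instances, family,
                                    orientation = c("sense", "antisense"),
                                    eps = 0.5, clip_total = NULL,
                                    null_total = NULL) {
  orientation <- match.arg(orientation)
  te <- data.table::as.data.table(te_instances)
  .fam <- family
  inst <- te[te$family == .fam]
  if (nrow(inst) == 0L) stopf("family '%s' has no instances", family)
  clen <- max(inst$cons_length)
  clip_total <- clip_total %||% sum(clip$weight)
  null_total <- null_total %||% sum(null$weight)
  cm <- consensus_base_map(clip, te, family, orientation)
  nm <- consensus_base_map(null, te, family, orientation)
  acc <- function(m) {
    v <- numeric(clen)
    if (nrow(m)) {
      s <- rowsum(m$weight, m$cons_pos)
      v[as.integer(rownames(s))] <- s[, 1L]
    }
    v
  }
  clip_cov <- acc(cm)
  null_cov <- acc(nm)
  ratio <- ((clip_cov + eps) / (null_cov + eps)) * (null_total / clip_total)
  structure(list(family = family, orientation = orientation,
                 cons_length = clen, clip_cov = clip_cov, null_cov = null_cov,
                 norm_ratio = ratio, clip_total = clip_total,
                 null_total = null_total),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus_profile: %s (%s), %d nt, max ratio %.2f\n",
              x$family, x$orientation, x$cons_length, max(x$norm_ratio)))
  invisible(x)
}

#' Segment a consensus profile into TE-specific motifs (TESMs)
#'
#' Maximal runs of consensus positions whose normalised CLIP/null coverage
#' ratio exceeds `fold` become peak spans. Each span yields one 9-column PWM
#' anchored at its maximum-CLIP-coverage position (leftmost on ties); windows
#' clipped by a consensus edge are discarded. Column frequencies are the
#' weighted nucleotide frequencies of the read bases covering each consensus
#' column (plus a pseudocount), read 5'->3' along the bound RNA: for the
#' antisense orientation the columns run along decreasing consensus positions
#' with complemented bases.
#'
#' @param profile a `consensus_profile`.
#' @param clip the CLIP alignment table the profile was built from.
#' @param te_instances TE instance table.
#' @param genome genome sequences (for read base lookup; exact-matching reads
#'   carry the reference base at every aligned position).
#' @param fold ratio threshold (default 3).
#' @param pseudocount per-cell PWM pseudocount (default 0.01).
#' @return a `tesm_set`: list with `meta` (data.table: tesm_id, family,
#'   orientation, span_start, span_end, anchor, support, enrichment) and
#'   `pwms` (named list of 4 x 9 matrices, rows A/C/G/T).
#' @export
segment_tesms <- function(profile, clip, te_instances, genome, fold = 3,
                          pseudocount = 0.01) {
  stopifnot(inherits(profile, "consensus_profile"))
  above <- profile$norm_ratio > fold
  meta <- list(); pwms <- list()
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    spans <- data.table::data.table(start = starts[r$values],
                                    end = ends[r$values])
    bm <- consensus_base_map(clip, te_instances, profile$family,
                             profile$orientation)
    if (nrow(bm)) {
      chars <- lapply(chrom_lengths(genome), function(i) NULL)
      for (cn in unique(bm$chrom))
        chars[[cn]] <- str_chars(chrom_string(genome, cn))
      b <- character(nrow(bm))
      for (cn in unique(bm$chrom)) {
        i <- which(bm$chrom == cn)
        b[i] <- chars[[cn]][bm$gpos[i]]
      }
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      minus <- bm$read_strand == "-"
      b[minus] <- comp[b[minus]]
      bm[, base := b]
    }
    ki <- 0L
    for (sp in seq_len(nrow(spans))) {
      lo <- spans$start[sp]; hi <- spans$end[sp]
      anchor <- lo + which.max(profile$clip_cov[lo:hi]) - 1L
      w1 <- anchor - 4L; w2 <- anchor + 4L
      if (w1 < 1L || w2 > profile$cons_length) next  # edge-clipped: discard
      cols <- if (profile$orientation == "sense") w1:w2 else w2:w1
      sub <- bm[cons_pos >= w1 & cons_pos <= w2]
      if (nrow(sub) == 0L) next
      pwm <- matrix(pseudocount, 4L, 9L,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      for (ci in seq_along(cols)) {
        cs <- sub[cons_pos == cols[ci] & base %in% c("A", "C", "G", "T")]
        if (nrow(cs)) {
          f <- rowsum(cs$weight, cs$base)
          pwm[rownames(f), ci] <- pwm[rownames(f), ci] + f[, 1L]
        }
      }
      pwm <- sweep(pwm, 2L, colSums(pwm), "/")
      support <- sub[, sum(weight[!duplicated(aln_id)])]
      enr <- mean(profile$norm_ratio[w1:w2])
      ki <- ki + 1L
      id <- sprintf("%s_%s_%d", profile$family,
                    substr(profile$orientation, 1L, 4L), anchor)
      meta[[ki]] <- data.table::data.table(
        tesm_id = id, family = profile$family,
        orientation = profile$orientation,
        span_start = lo, span_end = hi, anchor = anchor,
        support = support, enrichment = enr)
      pwms[[id]] <- pwm
    }
  }
  meta <- if (length(meta)) data.table::rbindlist(meta) else
    data.table::data.table(tesm_id = character(0), family = character(0),
                           orientation = character(0), span_start = integer(0),
                           span_end = integer(0), anchor = integer(0),
                           support = numeric(0), enrichment = numeric(0))
  structure(list(meta = meta, pwms = pwms), class = "tesm_set")
}

#' @export
print.tesm_set <- function(x, ...) {
  cat(sprintf("tesm_set: %d motifs\n", nrow(x$meta)))
  if (nrow(x$meta)) {
    cons <- vapply(x$pwms[x$meta$tesm_id], pwm_consensus, character(1))
    print(cbind(x$meta[, .(tesm_id, family, orientation, enrichment)],
                consensus = cons))
  }
  invisible(x)
}

#' Consensus string of a PWM (column argmax)
#'
#' @param pwm 4 x n matrix with rows A/C/G/T.
#' @return character string of length n.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2L, which.max)], collapse = "")
}

#' Combine several tesm_sets into one
#'
#' @param ... `tesm_set` objects (or a list of them).
#' @return a single `tesm_set`.
#' @export
combine_tesms <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "tesm_set")) xs <- xs[[1]]
  xs <- unname(xs)
  meta <- data.table::rbindlist(lapply(xs, `[[`, "meta"))
  pwms <- do.call(c, unname(lapply(xs, `[[`, "pwms")))
  structure(list(meta = meta, pwms = pwms), class = "tesm_set")
}
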