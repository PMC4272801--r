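# TE family-by-orientation enrichment of CLIP alignments over the
# transcript-abundance null model.

# stratum of each TE instance: mRNA-exon > lncRNA-exon > intron > intergenic
classify_te_strata <- function(te, isoforms) {
  te <- data.table::as.data.table(te)
  iso <- data.table::as.data.table(isoforms)
  ex <- iso[feature == "exon" & is_pre_rna == FALSE,
            .(chrom, start, end, biotype)]
  spans <- iso[feature == "exon",
               .(start = min(start), end = max(end)), by = .(gene_id, chrom)]
  te[, idx := .I]
  out <- rep("intergenic", nrow(te))
  if (nrow(spans)) {
    data.table::setkey(spans, chrom, start, end)
    q <- te[, .(idx, chrom, start, end)]
    data.table::setkey(q, chrom, start, end)
    hit <- data.table::foverlaps(q, spans, type = "any", nomatch = NULL)
    out[unique(hit$idx)] <- "intron"
  }
  if (nrow(ex)) {
    data.table::setkey(ex, chrom, start, end)
    q <- te[, .(idx, chrom, start, end)]
    data.table::setkey(q, chrom, start, end)
    hit <- data.table::foverlaps(q, ex, type = "any", nomatch = NULL)
    ln <- hit[biotype == "lncRNA", unique(idx)]
    mr <- hit[biotype == "mRNA", unique(idx)]
    out[ln] <- "lncRNA-exon"
    out[mr] <- "mRNA-exon"   # mRNA exon takes precedence
  }
  te[, idx := NULL]
  out
}

# weighted any-base overlap of alignments with TE instances;
# one contribution per (alignment, family, orientation)
te_overlap_weights <- function(aln, te) {
  bl <- alignment_blocks(aln)
  if (nrow(bl) == 0L) {
    return(data.table::data.table(family = character(0),
                                  orientation = character(0),
                                  stratum = character(0), w = numeric(0)))
  }
  tq <- data.table::as.data.table(te)
  tq[, te_i := .I]
  data.table::setkey(tq, chrom, start, end)
  data.table::setkey(bl, chrom, start, end)
  ov <- data.table::foverlaps(bl, tq, type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) {
    return(data.table::data.table(family = character(0),
                                  orientation = character(0),
                                  stratum = character(0), w = numeric(0)))
  }
  ov[, orientation := data.table::fifelse(i.strand == strand,
                                          "sense", "antisense")]
  ov <- unique(ov[, .(aln_id, family, orientation, stratum, weight)],
               by = c("aln_id", "family", "orientation", "stratum"))
  ov[, .(family, orientation, stratum, w = weight)]
}

#' TE family-by-orientation enrichment against the null model
#'
#' Counts weighted CLIP and null alignments overlapping (any base) the
#' instances of every TE family, split by orientation (read strand vs TE
#' strand) and annotation stratum, and reports the log2 ratio of the two
#' library-normalised proportions. When either weight is zero, a pseudo-weight
#' of 1 is added to both counts before forming the ratio.
#'
#' @param clip,null weighted, duplicate-capped alignment tables.
#' @param te_instances TE instance table.
#' @param isoforms optional exon table used to stratify instances into
#'   mRNA-exon / lncRNA-exon / intron; without it only the `all` stratum is
#'   reported.
#' @param pseudo pseudo-weight for zero counts (default 1).
#' @return data.table of enrichment records: family, orientation, stratum
#'   (`all` plus specific strata), clip_weight, null_weight, clip_total,
#'   null_total, log2_ratio.
#' @export
compute_enrichment <- function(clip, null, te_instances, isoforms = NULL,
                               pseudo = 1) {
  te <- data.table::as.data.table(te_instances)
  if (nrow(te) == 0L) stopf("no TE instances given")
  if (any(is.na(te$family) | !nzchar(te$family)))
    stopf("unknown (empty) family in the TE instance list")
  te[, stratum := if (is.null(isoforms)) "all" else
    classify_te_strata(te, isoforms)]
  clip_total <- sum(clip$weight)
  null_total <- sum(null$weight)
  cw <- te_overlap_weights(clip, te)
  nw <- te_overlap_weights(null, te)
  agg <- function(x) {
    spec <- x[, .(w = sum(w)), by = .(family, orientation, stratum)]
    all_ <- x[, .(w = sum(w), stratum = "all"), by = .(family, orientation)]
    rbind(spec[stratum != "all"], all_)
  }
  cagg <- agg(cw); nagg <- agg(nw)
  strata <- unique(c("all", te$stratum))
  grid <- data.table::CJ(family = unique(te$family),
                         orientation = c("sense", "antisense"),
                         stratum = strata, unique = TRUE)
  grid <- merge(grid, cagg, by = c("family", "orientation", "stratum"),
                all.x = TRUE)
  data.table::setnames(grid, "w", "clip_weight")
  grid <- merge(grid, nagg, by = c("family", "orientation", "stratum"),
                all.x = TRUE)
  data.table::setnames(grid, "w", "null_weight")
  grid[is.na(clip_weight), clip_weight := 0]
  grid[is.na(null_weight), null_weight := 0]
  grid[, `:=`(clip_total = clip_total, null_total = null_total)]
  zero <- grid$clip_weight == 0 | grid$null_weight == 0
  cw_ <- grid$clip_weight + pseudo * zero
  nw_ <- grid$null_weight + pseudo * zero
  grid[, log2_ratio := log2((cw_ / clip_total) / (nw_ / null_total))]
  data.table::setorder(grid, stratum, family, orientation)
  grid[]
}

#' Binomial significance test for enrichment records
#'
#' Two-sided exact binomial test of the (rounded) clip count against the null
#' proportion, with Benjamini-Hochberg adjustment across all
#' (family, orientation) pairs within each stratum.
#'
#' @param records enrichment table from [compute_enrichment()].
#' @return the table with `p_value` and `q_value` columns appended.
#' @export
test_enrichment_significance <- function(records) {
  dt <- data.table::as.data.table(records)
  if (any(dt$null_total <= 0)) stopf("null library size is zero")
  dt[, p_value := {
    mapply(function(x, n, nw, nt) {
      x <- round(x); n <- max(1, round(n))
      p0 <- nw / nt
      if (p0 <= 0) {
        if (x == 0) 1 else stats::binom.test(x, n, p = .Machine$double.eps,
                                             alternative = "two.sided")$p.value
      } else if (p0 >= 1) {
        1
      } else {
        stats::binom.test(x, n, p = p0, alternative = "two.sided")$p.value
      }
    }, clip_weight, clip_total, null_weight, null_total)
  }]
  dt[, q_value := stats::p.adjust(p_value, method = "BH"), by = stratum]
  dt[]
}
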