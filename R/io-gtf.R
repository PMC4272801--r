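# GTF reading/writing (GENCODE-dialect attributes) and pre-RNA augmentation.
#
# Internal exon tables hold one row per feature with columns:
#   gene_id, isoform_id, chrom, strand, start, end (1-based closed),
#   feature ("exon" or "CDS"), biotype ("mRNA" or "lncRNA"), is_pre_rna.

#' Read gene annotation from GTF
#'
#' Parses `exon` and `CDS` features and their `gene_id`/`transcript_id`
#' attributes. Biotypes are taken from `gene_biotype`/`gene_type` when present
#' (`protein_coding` maps to `mRNA`, anything containing "lnc" to `lncRNA`);
#' the default is `mRNA`. Exons of one transcript must be non-overlapping.
#'
#' @param path GTF file.
#' @return data.table exon/CDS table (see above), exons sorted by coordinate.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stopf("no records in %s", path)
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 9) stopf("malformed GTF: fewer than 9 fields at line %d",
                           lineno[1])
  dt <- data.table::data.table(
    chrom = f[[1]], feature = f[[3]],
    start = suppressWarnings(as.integer(f[[4]])),
    end = suppressWarnings(as.integer(f[[5]])),
    strand = f[[7]], attr = f[[9]], line = lineno
  )
  dt <- dt[feature %in% c("exon", "CDS")]
  if (!nrow(dt)) stopf("no exon/CDS records in %s", path)

  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, ' "[^"]*"'), a))
    out <- rep(NA_character_, length(a))
    hit <- regexpr(paste0(key, ' "[^"]*"'), a)
    ok <- hit > 0
    out[ok] <- sub(paste0(key, ' "([^"]*)"'), "\\1",
                   regmatches(a, hit))
    out
  }
  dt[, gene_id := get_attr(attr, "gene_id")]
  dt[, isoform_id := get_attr(attr, "transcript_id")]
  bad <- which(is.na(dt$gene_id) | is.na(dt$isoform_id))
  if (length(bad))
    stopf("malformed GTF attributes (missing gene_id/transcript_id) at line %d",
          dt$line[bad[1]])
  bt <- get_attr(dt$attr, "gene_biotype")
  bt2 <- get_attr(dt$attr, "gene_type")
  bt[is.na(bt)] <- bt2[is.na(bt)]
  dt[, biotype := data.table::fifelse(
    grepl("lnc", bt %||% "", ignore.case = TRUE), "lncRNA", "mRNA")]
  dt[is.na(bt), biotype := "mRNA"]
  dt[, is_pre_rna := FALSE]
  dt[, attr := NULL]

  # invariant: exons of one transcript are non-overlapping
  ex <- dt[feature == "exon"]
  data.table::setorder(ex, isoform_id, start)
  ovl <- ex[, any(start[-1] <= cummax(end)[-.N]), by = isoform_id]
  if (any(ovl$V1))
    stopf("overlapping exon records for transcript '%s'",
          ovl$isoform_id[which(ovl$V1)[1]])
  dt[, line := NULL]
  data.table::setorder(dt, chrom, gene_id, isoform_id, feature, start)
  dt[]
}

#' Write an exon table to GTF
#'
#' @param isoforms exon/CDS table as returned by [read_gtf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(isoforms, path) {
  dt <- data.table::as.data.table(isoforms)[is_pre_rna == FALSE]
  data.table::setorder(dt, chrom, start, isoform_id, feature)
  bt <- data.table::fifelse(dt$biotype == "lncRNA", "lncRNA", "protein_coding")
  lines <- sprintf(
    '%s\tretroclip\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    dt$chrom, dt$feature, dt$start, dt$end, dt$strand,
    dt$gene_id, dt$isoform_id, bt)
  writeLines(lines, path)
  invisible(path)
}

#' Augment an annotation with unspliced pre-RNA isoforms
#'
#' For every gene, adds one single-exon isoform (`<gene_id>.pre`) spanning the
#' gene locus from its leftmost to rightmost exon base, so intronic reads have
#' a compatible transcript during abundance estimation and peak calling.
#'
#' @param isoforms exon table.
#' @return exon table with pre-RNA rows appended (`is_pre_rna == TRUE`).
#' @export
augment_pre_rna <- function(isoforms) {
  dt <- data.table::as.data.table(isoforms)
  if (any(dt$is_pre_rna)) return(dt[])
  pre <- dt[feature == "exon",
            .(isoform_id = paste0(gene_id[1], ".pre"),
              chrom = chrom[1], strand = strand[1],
              start = min(start), end = max(end),
              feature = "exon", biotype = biotype[1], is_pre_rna = TRUE),
            by = gene_id]
  out <- rbind(dt, pre, use.names = TRUE)
  data.table::setorder(out, chrom, gene_id, isoform_id, feature, start)
  out[]
}
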