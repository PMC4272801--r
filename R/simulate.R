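# Synthetic-data generator: toy genomes with TE insertions, multi-isoform
# genes, CLIP-like stranded reads with planted binding signal, conservation
# tracks and knockdown statistic tables, all with recorded ground truth.

#' Default TE family panel for simulations
#'
#' Twelve families loosely shaped like the major human repeat classes (SINE-,
#' LINE-, LTR- and DNA-transposon-sized consensus lengths; LINE-like families
#' get high 5'-truncation rates). Consensus sequences are drawn at simulation
#' time from the configured seed.
#'
#' @return data.table with columns `name`, `cons_length`, `n_copies`,
#'   `truncation_rate`, `substitution_rate`.
#' @export
default_te_families <- function() {
  data.table::data.table(
    name = c("AluY", "AluSx", "L1", "L1MC4a", "L2", "MIR", "ERVL", "ERV1",
             "MaLR", "Tigger1", "Charlie1", "THE1"),
    cons_length = c(300L, 300L, 1500L, 800L, 500L, 260L, 600L, 700L, 450L,
                    900L, 600L, 350L),
    n_copies = c(40L, 30L, 12L, 12L, 20L, 25L, 10L, 8L, 12L, 8L, 10L, 12L),
    truncation_rate = c(0.1, 0.1, 0.8, 0.6, 0.3, 0.2, 0.2, 0.2, 0.2, 0.2,
                        0.2, 0.2),
    substitution_rate = c(0.05, 0.08, 0.08, 0.08, 0.08, 0.08, 0.1, 0.1, 0.1,
                          0.1, 0.1, 0.1)
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' 400 kb two-chromosome genome carrying the [default_te_families()] panel,
#' 80 multi-isoform genes, lognormal transcript abundances spanning orders of
#' magnitude, 36-nt reads with a 3' sequencing adapter, 15% PCR duplicates and
#' no planted signal.
#'
#' @param seed integer RNG seed; the whole simulation is deterministic given it.
#' @param n_chroms,chrom_len genome shape.
#' @param te_families data.frame like [default_te_families()]; an optional
#'   `consensus` column supplies explicit consensus sequences.
#' @param n_genes,isoforms_per_gene annotation shape; `n_genes` is an upper
#'   bound, tiling stops when the genome is full.
#' @param lncrna_fraction fraction of genes labelled lncRNA (no CDS).
#' @param n_exons_range,exon_len_range,intron_len_range gene geometry
#'   (uniform draws within each range, nt).
#' @param te_exon_fraction probability that a TE copy overlapping an exon is
#'   accepted rather than re-placed; 1 (default) places copies independently
#'   of the annotation, 0 emulates strong purifying selection against
#'   exonic insertions.
#' @param abundance_meanlog,abundance_sdlog lognormal isoform expression model.
#' @param pre_rna_rel_abundance abundance of the unspliced pre-RNA relative to
#'   a fresh lognormal draw (controls intronic background).
#' @param planted_motifs data.frame with columns `motif` (9-mer), `family`
#'   (TE family name or `"nonrepetitive"`), `multiplier` (binding enrichment
#'   multiplier, >= 1) and `n_nonrep` (number of nonrepetitive genomic copies
#'   of the motif to plant). Family-targeted motifs are written into the
#'   family consensus so every copy inherits them.
#' @param family_enrichment named numeric vector, family -> multiplier; read
#'   starts within any instance of the family are upweighted by it (whole-span
#'   binding channel, distinct from the motif channel).
#' @param read_len read length (>= 20).
#' @param n_reads number of reads to emit.
#' @param insert_min minimum insert length; inserts are uniform between
#'   `insert_min` and `read_len`, shorter inserts are padded with the adapter.
#' @param adapter 3' adapter sequence.
#' @param pcr_duplicate_rate expected fraction of reads that are PCR copies.
#' @param conservation_delta score added to the conservation baseline at
#'   planted nonrepetitive motif instances.
#' @return a `retroclip_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              chrom_len = 200000L,
                              te_families = default_te_families(),
                              n_genes = 80L,
                              isoforms_per_gene = 2L,
                              lncrna_fraction = 0.2,
                              n_exons_range = c(2L, 4L),
                              exon_len_range = c(150L, 400L),
                              intron_len_range = c(300L, 1200L),
                              te_exon_fraction = 1,
                              abundance_meanlog = 0,
                              abundance_sdlog = 1.5,
                              pre_rna_rel_abundance = 0.15,
                              planted_motifs = NULL,
                              family_enrichment = numeric(0),
                              read_len = 36L,
                              n_reads = 50000L,
                              insert_min = 24L,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              pcr_duplicate_rate = 0.15,
                              conservation_delta = 1) {
  te_families <- data.table::as.data.table(te_families)
  if (is.null(planted_motifs)) {
    planted_motifs <- data.table::data.table(
      motif = character(0), family = character(0), multiplier = numeric(0),
      n_nonrep = integer(0))
  } else {
    planted_motifs <- data.table::as.data.table(planted_motifs)
    if (is.null(planted_motifs$n_nonrep)) planted_motifs[, n_nonrep := 0L]
    if (any(nchar(planted_motifs$motif) != 9L))
      stopf("planted motifs must be 9-mers")
    if (any(planted_motifs$multiplier < 1))
      stopf("binding enrichment multipliers must be >= 1")
    known <- planted_motifs$family %in% c(te_families$name, "nonrepetitive")
    if (!all(known))
      stopf("unknown planted-motif target '%s'",
            planted_motifs$family[!known][1])
  }
  rates <- c(te_families$truncation_rate, te_families$substitution_rate,
             pcr_duplicate_rate, lncrna_fraction)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  if (read_len < 20L) stopf("read_len must be >= 20")
  if (length(family_enrichment) && any(family_enrichment < 1))
    stopf("family enrichment multipliers must be >= 1")
  if (insert_min < 20L || insert_min > read_len)
    stopf("insert_min must lie in [20, read_len]")
  if (te_exon_fraction < 0 || te_exon_fraction > 1)
    stopf("te_exon_fraction must lie in [0, 1]")
  structure(list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_len = as.integer(chrom_len), te_families = te_families,
    n_genes = as.integer(n_genes),
    isoforms_per_gene = as.integer(isoforms_per_gene),
    lncrna_fraction = lncrna_fraction,
    n_exons_range = as.integer(n_exons_range),
    exon_len_range = as.integer(exon_len_range),
    intron_len_range = as.integer(intron_len_range),
    te_exon_fraction = te_exon_fraction,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    pre_rna_rel_abundance = pre_rna_rel_abundance,
    planted_motifs = planted_motifs,
    family_enrichment = family_enrichment,
    read_len = as.integer(read_len), n_reads = as.integer(n_reads),
    insert_min = as.integer(insert_min), adapter = adapter,
    pcr_duplicate_rate = pcr_duplicate_rate,
    conservation_delta = conservation_delta
  ), class = "retroclip_config")
}

#' Simulate a toy genome with TE insertions and a multi-isoform annotation
#'
#' Places TE copies (random strand, 5'-truncated at the configured rate,
#' mutated at the per-copy substitution rate) into random chromosomes, tiles
#' the genome with multi-exon genes, plants the configured motifs, and records
#' the ground truth. Family-targeted planted motifs are embedded in the family
#' consensus; nonrepetitive copies are written into gene bodies outside TEs on
#' the gene strand. The truth table `motif_sites` lists every exact RNA-sense
#' occurrence of each planted 9-mer within gene spans.
#'
#' @param config a [simulation_config()].
#' @return a `retroclip_sim` list with `genome` (DNAStringSet), `consensi`
#'   (DNAStringSet), `te_instances`, `isoforms` (exon/CDS table) and `truth`
#'   (list with `motif_sites`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "retroclip_config"))
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  fams <- data.table::copy(config$te_families)
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  # chromosomes as character vectors during construction (in-place edits),
  # assembled into strings at the end
  chrom_chars <- lapply(chrom_names, function(cn)
    sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE))
  names(chrom_chars) <- chrom_names

  # consensus sequences (drawn where not supplied), with family-targeted
  # motifs planted mid-consensus
  if (is.null(fams$consensus)) fams[, consensus := NA_character_]
  miss <- which(is.na(fams$consensus))
  if (length(miss))
    fams$consensus[miss] <- random_dna(length(miss), fams$cons_length[miss])
  if (any(nchar(fams$consensus) != fams$cons_length))
    stopf("supplied consensus length disagrees with cons_length for '%s'",
          fams$name[nchar(fams$consensus) != fams$cons_length][1])
  pm <- config$planted_motifs
  for (i in seq_len(nrow(pm))) {
    if (pm$family[i] == "nonrepetitive") next
    j <- which(fams$name == pm$family[i])
    at <- (fams$cons_length[j] - 9L) %/% 2L + 1L
    s <- fams$consensus[j]
    substr(s, at, at + 8L) <- pm$motif[i]
    fams$consensus[j] <- s
  }

  # tile genes over the genome (before TE placement, so insertion can be
  # biased away from exons when te_exon_fraction < 1)
  gene_rows <- list()
  gi <- 0L
  exr <- config$n_exons_range
  elr <- config$exon_len_range
  ilr <- config$intron_len_range
  for (cn in chrom_names) {
    pos <- 1L + sample(200:800, 1L)
    while (gi < config$n_genes && pos < config$chrom_len - 2000L) {
      n_ex <- sample(exr[1]:exr[2], 1L)
      ex_len <- sample(elr[1]:elr[2], n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(ilr[1]:ilr[2], n_ex - 1L,
                                     replace = TRUE)
                else integer(0)
      starts <- pos + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ends <- starts + ex_len - 1L
      if (ends[n_ex] > config$chrom_len - 200L) break
      gi <- gi + 1L
      gene_rows[[gi]] <- data.table::data.table(
        gene_id = sprintf("g%03d", gi), chrom = cn,
        strand = sample(c("+", "-"), 1L),
        start = starts, end = ends, exon_n = seq_len(n_ex),
        biotype = if (runif(1) < config$lncrna_fraction) "lncRNA" else "mRNA")
      pos <- ends[n_ex] + sample(200:800, 1L)
    }
    if (gi >= config$n_genes) break
  }
  if (gi == 0L) stopf("genome too small to place any gene")
  genes <- data.table::rbindlist(gene_rows)
  exon_iv <- genes[, .(chrom, start, end)]

  # place TE copies
  total_te <- sum(fams$n_copies * fams$cons_length)
  if (total_te > 0.6 * config$n_chroms * config$chrom_len)
    stopf("TE copy number too large for the genome size")
  occupied <- data.table::data.table(chrom = character(0), start = integer(0),
                                     end = integer(0))
  te_rows <- vector("list", sum(fams$n_copies))
  ti <- 0L
  for (j in seq_len(nrow(fams))) {
    clen <- fams$cons_length[j]
    for (cp in seq_len(fams$n_copies[j])) {
      cons_start <- if (runif(1) < fams$truncation_rate[j])
        sample.int(clen, 1L) else 1L
      cons_end <- clen
      seg <- substr(fams$consensus[j], cons_start, cons_end)
      slen <- nchar(seg)
      # substitutions
      nsub <- rbinom(1L, slen, fams$substitution_rate[j])
      if (nsub > 0L) {
        at <- sample.int(slen, nsub)
        old <- substring(seg, at, at)
        new <- vapply(old, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        for (q in seq_along(at)) substr(seg, at[q], at[q]) <- new[q]
      }
      strand <- sample(c("+", "-"), 1L)
      gseq <- if (strand == "-") revcomp(seg) else seg
      # rejection-sample a free interval, optionally avoiding exons
      placed <- FALSE
      for (try in 1:500) {
        cn <- sample(chrom_names, 1L)
        st <- sample.int(config$chrom_len - slen - 1L, 1L)
        en <- st + slen - 1L
        hit <- occupied[chrom == cn & start <= en & end >= st]
        if (nrow(hit) > 0L) next
        if (config$te_exon_fraction < 1) {
          in_exon <- nrow(exon_iv[chrom == cn & start <= en & end >= st]) > 0L
          if (in_exon && runif(1) >= config$te_exon_fraction) next
        }
        chrom_chars[[cn]][st:en] <- str_chars(gseq)
        occupied <- rbind(occupied,
                          data.table::data.table(chrom = cn, start = st,
                                                 end = en))
        ti <- ti + 1L
        te_rows[[ti]] <- data.table::data.table(
          chrom = cn, start = st, end = en, strand = strand,
          family = fams$name[j], subfamily = fams$name[j],
          cons_start = cons_start, cons_end = cons_end, cons_length = clen)
        placed <- TRUE
        break
      }
      if (!placed) stopf("could not place TE copy: genome too crowded")
    }
  }
  te <- data.table::rbindlist(te_rows[seq_len(ti)])
  data.table::setorder(te, chrom, start)

  # isoforms: t1 = all exons; further isoforms drop one internal exon
  iso_rows <- list()
  k <- 0L
  for (g in split(genes, by = "gene_id")) {
    n_ex <- nrow(g)
    k <- k + 1L
    iso_rows[[k]] <- data.table::data.table(
      gene_id = g$gene_id[1], isoform_id = paste0(g$gene_id[1], ".t1"),
      chrom = g$chrom[1], strand = g$strand[1],
      start = g$start, end = g$end, feature = "exon",
      biotype = g$biotype[1], is_pre_rna = FALSE)
    if (config$isoforms_per_gene >= 2L && n_ex >= 3L) {
      dropped <- sample(2:(n_ex - 1L),
                        min(config$isoforms_per_gene - 1L, n_ex - 2L))
      for (d in seq_along(dropped)) {
        gg <- g[-dropped[d]]
        k <- k + 1L
        iso_rows[[k]] <- data.table::data.table(
          gene_id = g$gene_id[1],
          isoform_id = sprintf("%s.t%d", g$gene_id[1], d + 1L),
          chrom = g$chrom[1], strand = g$strand[1],
          start = gg$start, end = gg$end, feature = "exon",
          biotype = g$biotype[1], is_pre_rna = FALSE)
      }
    }
  }
  isoforms <- data.table::rbindlist(iso_rows)

  # CDS for mRNAs: strand-aware last 40% of the terminal exon is 3'UTR
  cds_rows <- list()
  ci <- 0L
  for (g in split(genes, by = "gene_id")) {
    if (g$biotype[1] != "mRNA") next
    if (g$strand[1] == "+") {
      term <- which.max(g$start)
      u_len <- as.integer(floor(0.4 * (g$end[term] - g$start[term] + 1L)))
      utr <- c(g$end[term] - u_len + 1L, g$end[term])
    } else {
      term <- which.min(g$start)
      u_len <- as.integer(floor(0.4 * (g$end[term] - g$start[term] + 1L)))
      utr <- c(g$start[term], g$start[term] + u_len - 1L)
    }
    iso_g <- isoforms[gene_id == g$gene_id[1]]
    for (iso in split(iso_g, by = "isoform_id")) {
      for (e in seq_len(nrow(iso))) {
        s <- iso$start[e]; en <- iso$end[e]
        # subtract the UTR interval
        if (en < utr[1] || s > utr[2]) {
          ci <- ci + 1L
          cds_rows[[ci]] <- data.table::data.table(
            gene_id = iso$gene_id[1], isoform_id = iso$isoform_id[1],
            chrom = iso$chrom[1], strand = iso$strand[1],
            start = s, end = en, feature = "CDS",
            biotype = "mRNA", is_pre_rna = FALSE)
        } else if (s < utr[1] || en > utr[2]) {
          if (s < utr[1]) {
            ci <- ci + 1L
            cds_rows[[ci]] <- data.table::data.table(
              gene_id = iso$gene_id[1], isoform_id = iso$isoform_id[1],
              chrom = iso$chrom[1], strand = iso$strand[1],
              start = s, end = utr[1] - 1L, feature = "CDS",
              biotype = "mRNA", is_pre_rna = FALSE)
          }
          if (en > utr[2]) {
            ci <- ci + 1L
            cds_rows[[ci]] <- data.table::data.table(
              gene_id = iso$gene_id[1], isoform_id = iso$isoform_id[1],
              chrom = iso$chrom[1], strand = iso$strand[1],
              start = utr[2] + 1L, end = en, feature = "CDS",
              biotype = "mRNA", is_pre_rna = FALSE)
          }
        }
      }
    }
  }
  if (ci > 0L)
    isoforms <- rbind(isoforms, data.table::rbindlist(cds_rows))
  data.table::setorder(isoforms, chrom, gene_id, isoform_id, feature, start)

  gene_spans <- isoforms[feature == "exon",
                         .(chrom = chrom[1], strand = strand[1],
                           start = min(start), end = max(end)),
                         by = gene_id]

  # plant nonrepetitive motif copies inside gene bodies, outside TEs
  planted <- data.table::data.table(chrom = character(0), start = integer(0),
                                    end = integer(0))
  for (i in seq_len(nrow(pm))) {
    n_make <- pm$n_nonrep[i]
    made <- 0L
    tries <- 0L
    while (made < n_make && tries < 50L * n_make + 100L) {
      tries <- tries + 1L
      g <- gene_spans[sample.int(nrow(gene_spans), 1L)]
      if (g$end - g$start < 60L) next
      st <- g$start + sample.int(g$end - g$start - 9L, 1L)
      en <- st + 8L
      if (nrow(te[chrom == g$chrom & start <= en & end >= st])) next
      if (nrow(planted[chrom == g$chrom & start <= en & end >= st])) next
      ins <- if (g$strand == "-") revcomp(pm$motif[i]) else pm$motif[i]
      chrom_chars[[g$chrom]][st:en] <- str_chars(ins)
      planted <- rbind(planted, data.table::data.table(
        chrom = g$chrom, start = st, end = en))
      made <- made + 1L
    }
    if (made < n_make)
      warnf("planted only %d of %d nonrepetitive copies of %s",
            made, n_make, pm$motif[i])
  }

  chroms <- vapply(chrom_chars, paste, character(1), collapse = "")

  # truth: every exact RNA-sense occurrence of each planted motif in gene spans
  motif_sites <- list()
  mi <- 0L
  for (i in seq_len(nrow(pm))) {
    for (gidx in seq_len(nrow(gene_spans))) {
      g <- gene_spans[gidx]
      seqg <- substr(chroms[[g$chrom]], g$start, g$end)
      rna <- if (g$strand == "-") revcomp(seqg) else seqg
      hits <- gregexpr(paste0("(?=", pm$motif[i], ")"), rna,
                       perl = TRUE)[[1]]
      if (hits[1] == -1L) next
      # collapse overlapping matches (e.g. within a poly-U tract) into one
      # site anchored at the central match of each run
      hits <- as.integer(hits)
      grp <- cumsum(c(1L, diff(hits) > 8L))
      hits <- vapply(split(hits, grp), function(h)
        h[ceiling(length(h) / 2)], integer(1))
      for (h in hits) {
        gs <- if (g$strand == "+") g$start + h - 1L else g$end - h - 7L
        ge <- gs + 8L
        ov <- te[chrom == g$chrom & start <= ge & end >= gs]
        mi <- mi + 1L
        motif_sites[[mi]] <- data.table::data.table(
          motif = pm$motif[i], target = pm$family[i],
          multiplier = pm$multiplier[i],
          chrom = g$chrom, start = gs, end = ge, strand = g$strand,
          gene_id = g$gene_id,
          in_te = nrow(ov) > 0L,
          te_family = if (nrow(ov)) ov$family[1] else NA_character_)
      }
    }
  }
  motif_sites <- if (mi) data.table::rbindlist(motif_sites) else
    data.table::data.table(motif = character(0), target = character(0),
                           multiplier = numeric(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), gene_id = character(0),
                           in_te = logical(0), te_family = character(0))

  structure(list(
    genome = Biostrings::DNAStringSet(chroms),
    consensi = Biostrings::DNAStringSet(
      stats::setNames(fams$consensus, fams$name)),
    te_instances = te,
    isoforms = isoforms,
    truth = list(motif_sites = motif_sites),
    config = config
  ), class = "retroclip_sim")
}

#' Simulate a conservation score track
#'
#' Baseline per-base scores are N(0, 1) over gene spans; planted motif
#' instances outside TEs get `conservation_delta` added, emulating selective
#' constraint at functional motif copies.
#'
#' @param sim a `retroclip_sim` from [simulate_genome()].
#' @param seed RNG seed (defaults to the simulation seed + 1).
#' @return a `score_track`.
#' @export
simulate_conservation_track <- function(sim, seed = NULL) {
  config <- sim$config
  seed <- seed %||% (config$seed + 1L)
  with_seed(seed, {
    cl <- chrom_lengths(sim$genome)
    spans <- data.table::as.data.table(sim$isoforms)[feature == "exon",
      .(start = min(start), end = max(end)), by = .(gene_id, chrom)]
    scores <- lapply(names(cl), function(cn) {
      v <- rep(NA_real_, cl[[cn]])
      d <- spans[chrom == cn]
      if (nrow(d)) {
        idx <- unique(sequence(d$end - d$start + 1L, from = d$start))
        v[idx] <- rnorm(length(idx))
      }
      v
    })
    names(scores) <- names(cl)
    ms <- sim$truth$motif_sites
    if (!is.null(ms) && nrow(ms)) {
      out_te <- ms[in_te == FALSE]
      for (i in seq_len(nrow(out_te))) {
        cn <- out_te$chrom[i]
        idx <- out_te$start[i]:out_te$end[i]
        base <- scores[[cn]][idx]
        base[is.na(base)] <- 0
        scores[[cn]][idx] <- base + config$conservation_delta
      }
    }
    score_track(scores)
  })
}
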