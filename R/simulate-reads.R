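# CLIP-like read simulation and knockdown statistic tables.

#' Simulate stranded CLIP-like reads with planted binding signal
#'
#' Reads are sampled from spliced isoforms plus internal unspliced pre-RNA
#' isoforms, with per-isoform fragment mass proportional to a lognormal
#' abundance draw times transcript length. Read start positions are uniform
#' along the transcript except that starts whose read covers the centre of a
#' planted motif occurrence are multiplied by the motif's enrichment
#' multiplier (so expected coverage peaks at the motif centre, like a
#' crosslink pile-up), and starts overlapping any instance of a family named
#' in `family_enrichment` are multiplied by that family's multiplier; weights
#' are renormalised over the whole library. Inserts are uniform between `insert_min` and `read_len`;
#' shorter inserts are padded with the 3' adapter and then random bases. PCR
#' duplicates are emitted at the configured rate. Every read (duplicates
#' included) carries a truth record with its source isoform, transcript start
#' and genomic blocks.
#'
#' @param sim a `retroclip_sim` from [simulate_genome()].
#' @param seed RNG seed (defaults to the simulation seed + 2).
#' @return list with `reads` (data.table: read_id, seq) and `truth`
#'   (data.table: read_id, isoform_id, gene_id, chrom, strand, tstart,
#'   insert_len, pos, blocks, is_duplicate, dup_of) plus `abundances`.
#' @export
simulate_clip_reads <- function(sim, seed = NULL) {
  config <- sim$config
  seed <- seed %||% (config$seed + 2L)
  with_seed(seed, simulate_clip_reads_impl(sim, config))
}

simulate_clip_reads_impl <- function(sim, config) {
  iso_all <- augment_pre_rna(sim$isoforms)
  chains <- isoform_chains(iso_all)
  ids <- names(chains)
  n_iso <- length(ids)
  lens <- vapply(chains, `[[`, numeric(1), "len")
  pre <- grepl("\\.pre$", ids)
  abund <- rlnorm(n_iso, config$abundance_meanlog, config$abundance_sdlog)
  abund[pre] <- abund[pre] * config$pre_rna_rel_abundance
  rl <- config$read_len

  txseq <- vapply(chains, function(ch) transcript_seq(sim$genome, ch),
                  character(1))

  # base start-position weights per isoform: uniform along the transcript,
  # scaled by fragment mass, with whole-span family enrichment windows
  te <- sim$te_instances
  fam_e <- config$family_enrichment
  ms <- sim$truth$motif_sites
  npos <- pmax(1L, lens - config$insert_min + 1L)
  wlist <- vector("list", n_iso)
  centers <- vector("list", n_iso)   # motif centers + multipliers per isoform
  for (i in seq_len(n_iso)) {
    ch <- chains[[i]]
    w <- rep(abund[i] * lens[i] / npos[i], npos[i])
    if (length(fam_e)) {
      fe <- te[family %in% names(fam_e) & chrom == ch$chrom &
                 start <= max(ch$ends) & end >= min(ch$starts)]
      for (j in seq_len(nrow(fe))) {
        tt <- genome_to_tx(ch, c(fe$start[j]:fe$end[j]))
        tt <- tt[!is.na(tt)]
        if (!length(tt)) next
        lo <- max(1L, min(tt) - rl + 1L)
        hi <- min(npos[i], max(tt))
        if (lo <= hi)
          w[lo:hi] <- w[lo:hi] * fam_e[[fe$family[j]]]
      }
    }
    cc <- NULL
    if (!is.null(ms) && nrow(ms)) {
      mg <- ms[chrom == ch$chrom & strand == ch$strand &
                 start <= max(ch$ends) & end >= min(ch$starts)]
      if (nrow(mg)) {
        t1 <- genome_to_tx(ch, mg$start)
        t2 <- genome_to_tx(ch, mg$end)
        ok <- !is.na(t1) & !is.na(t2) & abs(t2 - t1) == 8L
        if (any(ok))
          cc <- data.table::data.table(
            center = pmin(t1[ok], t2[ok]) + 4L,
            multiplier = mg$multiplier[ok])
      }
    }
    wlist[[i]] <- w
    centers[i] <- list(cc)   # NULL-safe assignment
  }
  wvec <- unlist(wlist, use.names = FALSE)
  off <- c(0L, cumsum(npos))
  iso_of <- rep(seq_len(n_iso), npos)

  n_dup <- rbinom(1L, config$n_reads, config$pcr_duplicate_rate)
  n_orig <- config$n_reads - n_dup

  # insert lengths first; reads covering a motif centre are upweighted by the
  # motif multiplier, which makes the expected coverage peak exactly at the
  # centre (crosslink-like pile-up) instead of a flat plateau
  ins <- sample(config$insert_min:rl, n_orig, replace = TRUE)
  pick <- integer(n_orig)
  has_centers <- any(!vapply(centers, is.null, logical(1)))
  for (v in unique(ins)) {
    sel <- which(ins == v)
    wv <- wvec
    if (has_centers) {
      for (i in seq_len(n_iso)) {
        cc <- centers[[i]]
        if (is.null(cc)) next
        for (j in seq_len(nrow(cc))) {
          lo <- max(1L, cc$center[j] - v + 1L)
          hi <- min(npos[i], cc$center[j])
          if (lo <= hi) {
            idx <- off[i] + lo:hi
            wv[idx] <- wv[idx] * cc$multiplier[j]
          }
        }
      }
    }
    pick[sel] <- sample.int(length(wv), length(sel), replace = TRUE,
                            prob = wv)
  }
  iso_i <- iso_of[pick]
  tstart <- pick - off[iso_i]
  ins <- pmin(ins, lens[iso_i] - tstart + 1L)

  # read sequences: insert + adapter + random fill
  insert_seq <- substr(txseq[iso_i], tstart, tstart + ins - 1L)
  short <- which(ins < rl)
  seqs <- insert_seq
  if (length(short)) {
    need <- rl - ins[short]
    pad <- substr(rep(config$adapter, length(short)), 1L, pmin(need,
                  nchar(config$adapter)))
    rest <- need - nchar(pad)
    fill <- character(length(short))
    fi <- which(rest > 0L)
    if (length(fi)) fill[fi] <- random_dna(length(fi), rest[fi])
    seqs[short] <- paste0(insert_seq[short], pad, fill)
  }

  # genomic blocks per read (vectorised; junction reads handled per read)
  g1 <- integer(n_orig); g2 <- integer(n_orig)
  for (i in unique(iso_i)) {
    sel <- which(iso_i == i)
    g1[sel] <- tx_to_genome(chains[[i]], tstart[sel])
    g2[sel] <- tx_to_genome(chains[[i]], tstart[sel] + ins[sel] - 1L)
  }
  lo <- pmin(g1, g2); hi <- pmax(g1, g2)
  single <- (hi - lo) == (ins - 1L)
  blocks <- character(n_orig)
  blocks[single] <- sprintf("%d:%d", lo[single], ins[single])
  for (r in which(!single)) {
    b <- tx_interval_to_blocks(chains[[iso_i[r]]], tstart[r],
                               tstart[r] + ins[r] - 1L)
    blocks[r] <- encode_blocks(b$start, b$end - b$start + 1L)
  }

  chrom_v <- vapply(chains, `[[`, character(1), "chrom")
  strand_v <- vapply(chains, `[[`, character(1), "strand")
  gene_v <- vapply(chains, `[[`, character(1), "gene_id")

  truth <- data.table::data.table(
    read_id = sprintf("r%07d", seq_len(n_orig)),
    isoform_id = ids[iso_i], gene_id = gene_v[iso_i],
    chrom = chrom_v[iso_i], strand = strand_v[iso_i],
    tstart = tstart, insert_len = ins, pos = lo, blocks = blocks,
    is_duplicate = FALSE, dup_of = NA_character_)
  reads <- data.table::data.table(read_id = truth$read_id, seq = seqs)

  if (n_dup > 0L) {
    src <- sample.int(n_orig, n_dup, replace = TRUE)
    dup_truth <- truth[src]
    dup_truth[, `:=`(read_id = sprintf("r%07d", n_orig + seq_len(n_dup)),
                     is_duplicate = TRUE, dup_of = truth$read_id[src])]
    truth <- rbind(truth, dup_truth)
    reads <- rbind(reads, data.table::data.table(
      read_id = dup_truth$read_id, seq = seqs[src]))
  }

  list(reads = reads, truth = truth,
       abundances = data.table::data.table(
         isoform_id = ids, gene_id = gene_v, length = lens,
         abundance = abund, is_pre_rna = pre))
}

#' Alignments implied by the simulation truth
#'
#' Converts per-read truth records into a weighted alignment table (each read
#' at its true locus, weight 1), bypassing the aligner. Useful for testing
#' downstream statistics in isolation.
#'
#' @param truth truth table from [simulate_clip_reads()].
#' @return alignment table.
#' @export
truth_alignments <- function(truth) {
  dt <- data.table::as.data.table(truth)
  data.table::data.table(
    read_id = dt$read_id, chrom = dt$chrom, strand = dt$strand,
    pos = dt$pos, aligned_len = dt$insert_len, blocks = dt$blocks,
    n_alignments = 1L, weight = 1)
}

#' Simulate per-gene binding-site counts by class
#'
#' Each gene is bound with probability `p_bound`; bound genes get sites in one
#' or two randomly chosen classes with 1 + Poisson(`mean_sites`) counts.
#'
#' @param n_genes number of genes.
#' @param classes character vector of site-class names.
#' @param p_bound probability a gene has any site.
#' @param mean_sites Poisson mean of extra sites per active class.
#' @param seed RNG seed.
#' @return data.table with `gene_id` and one count column per class.
#' @export
simulate_site_counts <- function(n_genes, classes, p_bound = 0.6,
                                 mean_sites = 0.8, seed = 1L) {
  with_seed(seed, {
    m <- matrix(0L, n_genes, length(classes),
                dimnames = list(NULL, classes))
    bound <- runif(n_genes) < p_bound
    for (i in which(bound)) {
      k <- sample(1:2, 1L)
      cl <- sample(classes, min(k, length(classes)))
      m[i, cl] <- 1L + rpois(length(cl), mean_sites)
    }
    out <- data.table::data.table(gene_id = sprintf("g%05d", seq_len(n_genes)))
    cbind(out, data.table::as.data.table(m))
  })
}

#' Simulate a knockdown differential-expression table
#'
#' The per-gene differential-expression statistic is
#' `sum_c beta[c] * log2(1 + n_sites[c]) + N(0, noise_sd^2)` (positive =
#' up in the knockdown). Splicing p-values are uniform under no effect; with
#' `beta_splice`, `splice_p = U^exp(sum_c beta_splice[c] * log2(1+n))`, so a
#' positive splicing effect shifts p-values towards zero.
#'
#' @param site_counts data.table from [simulate_site_counts()] (or real
#'   binding summaries): `gene_id` plus one count column per class.
#' @param beta named numeric vector of class effects on the expression
#'   statistic; names must be count columns.
#' @param beta_splice optional named numeric vector of class effects on
#'   splicing.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param isoforms optional annotation; when given, all gene ids must exist in
#'   it.
#' @return data.table with `gene_id`, `de_stat`, `splice_p`.
#' @export
simulate_knockdown_table <- function(site_counts, beta, beta_splice = NULL,
                                     noise_sd = 1, seed = 1L,
                                     isoforms = NULL) {
  sc <- data.table::as.data.table(site_counts)
  if (!is.null(isoforms)) {
    known <- unique(data.table::as.data.table(isoforms)$gene_id)
    if (!all(sc$gene_id %in% known))
      stopf("gene id '%s' not present in the annotation",
            sc$gene_id[!sc$gene_id %in% known][1])
  }
  if (!all(names(beta) %in% names(sc)))
    stopf("effect class '%s' is not a column of site_counts",
          setdiff(names(beta), names(sc))[1])
  n <- nrow(sc)
  eff <- rep(0, n)
  for (cl in names(beta))
    eff <- eff + beta[[cl]] * log2(1 + sc[[cl]])
  eff_s <- rep(0, n)
  if (!is.null(beta_splice)) {
    if (!all(names(beta_splice) %in% names(sc)))
      stopf("splicing effect class '%s' is not a column of site_counts",
            setdiff(names(beta_splice), names(sc))[1])
    for (cl in names(beta_splice))
      eff_s <- eff_s + beta_splice[[cl]] * log2(1 + sc[[cl]])
  }
  with_seed(seed, {
    data.table::data.table(
      gene_id = sc$gene_id,
      de_stat = eff + rnorm(n, 0, noise_sd),
      splice_p = runif(n)^exp(eff_s))
  })
}
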