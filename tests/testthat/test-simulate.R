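# Synthetic-data generator: determinism, truncation, duplicates, uniformity,
# planted signal, knockdown tables.

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 7L, n_chroms = 1L, chrom_len = 40000L,
                           n_genes = 10L, n_reads = 2000L,
                           te_families = default_te_families()[1:2])
  s1 <- simulate_genome(cfg); s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(as.data.frame(s1$te_instances),
                   as.data.frame(s2$te_instances))
  r1 <- simulate_clip_reads(s1); r2 <- simulate_clip_reads(s2)
  expect_identical(r1$reads$seq, r2$reads$seq)
})

test_that("full-length copies cover the whole consensus; uniform truncation halves it", {
  fams0 <- data.table::data.table(name = "T0", cons_length = 200L,
                                  n_copies = 10L, truncation_rate = 0,
                                  substitution_rate = 0)
  cfg <- simulation_config(seed = 2L, n_chroms = 1L, chrom_len = 60000L,
                           n_genes = 5L, te_families = fams0)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$te_instances$cons_start == 1L))
  expect_true(all(sim$te_instances$cons_end == 200L))

  # truncation rate 1 with a uniform cut: mean cons_start ~ cons_length / 2
  fams1 <- data.table::data.table(name = "T1", cons_length = 200L,
                                  n_copies = 500L, truncation_rate = 1,
                                  substitution_rate = 0)
  cfg1 <- simulation_config(seed = 3L, n_chroms = 2L, chrom_len = 200000L,
                            n_genes = 5L, te_families = fams1)
  sim1 <- simulate_genome(cfg1)
  m <- mean(sim1$te_instances$cons_start)
  se <- 200 / sqrt(12) / sqrt(500)       # sd of U(1,200) over 500 copies
  expect_lt(abs(m - 100.5), 4 * se)
})

test_that("PCR duplicate fraction matches the configured rate", {
  cfg <- simulation_config(seed = 5L, n_chroms = 1L, chrom_len = 60000L,
                           n_genes = 15L, n_reads = 10000L,
                           te_families = default_te_families()[1:2],
                           pcr_duplicate_rate = 0.5)
  rd <- simulate_clip_reads(simulate_genome(cfg))
  frac <- mean(rd$truth$is_duplicate)
  expect_lt(abs(frac - 0.5), 0.02)   # binomial 99.97% CI at n = 10,000
  # every duplicate copies an original byte for byte
  dup <- rd$truth[rd$truth$is_duplicate == TRUE, ]
  ori <- rd$truth[match(dup$dup_of, rd$truth$read_id), ]
  expect_identical(dup$pos, ori$pos)
  expect_identical(dup$blocks, ori$blocks)
})

test_that("without planted signal, coverage is uniform along a transcript", {
  # single gene, single exon: chi-square goodness of fit on read starts
  fams <- data.table::data.table(name = "T0", cons_length = 100L,
                                 n_copies = 1L, truncation_rate = 0,
                                 substitution_rate = 0)
  cfg <- simulation_config(seed = 8L, n_chroms = 1L, chrom_len = 30000L,
                           n_genes = 4L, n_reads = 50000L,
                           te_families = fams, pcr_duplicate_rate = 0,
                           pre_rna_rel_abundance = 1e-9)
  sim <- simulate_genome(cfg)
  rd <- simulate_clip_reads(sim)
  tr <- rd$truth
  one <- names(sort(table(tr$isoform_id), decreasing = TRUE))[1]
  st <- tr$tstart[tr$isoform_id == one]
  bins <- cut(st, breaks = 20)
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("a planted 10x motif yields >= 5-fold coverage at the window", {
  fams <- data.table::data.table(name = "T0", cons_length = 100L,
                                 n_copies = 1L, truncation_rate = 0,
                                 substitution_rate = 0)
  cfg <- simulation_config(seed = 12L, n_chroms = 1L, chrom_len = 30000L,
                           n_genes = 4L, n_reads = 50000L,
                           te_families = fams, pcr_duplicate_rate = 0,
                           pre_rna_rel_abundance = 0.05,
                           planted_motifs = data.frame(
                             motif = "ACCGTTAGC", family = "nonrepetitive",
                             multiplier = 10, n_nonrep = 4L))
  sim <- simulate_genome(cfg)
  rd <- simulate_clip_reads(sim)
  tr <- rd$truth
  ms <- sim$truth$motif_sites
  chains <- retroclip:::isoform_chains(augment_pre_rna(sim$isoforms))
  ratios <- c()
  for (i in seq_len(nrow(ms))) {
    s <- ms[i]
    for (id in names(chains)) {
      ch <- chains[[id]]
      if (ch$gene_id != s$gene_id) next
      tc <- genome_to_tx(ch, s$start + 4L)
      if (is.na(tc)) next
      sub <- tr[tr$isoform_id == id, ]
      if (nrow(sub) < 100L) next       # need a measurable baseline
      cov_ctr <- sum(sub$tstart <= tc & sub$tstart + sub$insert_len - 1L >= tc)
      base <- sum(sub$insert_len) / ch$len
      ratios <- c(ratios, cov_ctr / base)
    }
  }
  expect_gt(length(ratios), 0L)
  expect_gt(mean(ratios), 5)
})

test_that("knockdown table is standard normal when all effects are zero", {
  sc <- simulate_site_counts(2000L, c("TE_exon", "nonrep_intron"), seed = 4L)
  kd <- simulate_knockdown_table(sc, beta = c(TE_exon = 0, nonrep_intron = 0),
                                 seed = 5L)
  ks <- stats::ks.test(kd$de_stat, "pnorm")
  expect_gt(ks$p.value, 0.01)
  ksu <- stats::ks.test(kd$splice_p, "punif")
  expect_gt(ksu$p.value, 0.01)
})

test_that("equal planted effects leave TE-only and nonrep-only genes indistinguishable", {
  classes <- c("TE_intron", "nonrep_intron")
  sc <- simulate_site_counts(2000L, classes, seed = 6L)
  kd <- simulate_knockdown_table(sc, beta = c(TE_intron = 1, nonrep_intron = 1),
                                 seed = 7L)
  te_only <- sc$TE_intron > 0 & sc$nonrep_intron == 0
  nr_only <- sc$nonrep_intron > 0 & sc$TE_intron == 0
  ks <- stats::ks.test(kd$de_stat[te_only], kd$de_stat[nr_only])
  expect_gt(ks$p.value, 0.01)
})

test_that("opposite-sign class effects shift genes in opposite directions", {
  classes <- c("Alu_intron", "TE_intron")
  sc <- simulate_site_counts(2000L, classes, seed = 8L)
  kd <- simulate_knockdown_table(sc, beta = c(Alu_intron = -1, TE_intron = 1),
                                 seed = 9L)
  alu_only <- sc$Alu_intron > 0 & sc$TE_intron == 0
  te_only <- sc$TE_intron > 0 & sc$Alu_intron == 0
  expect_lt(median(kd$de_stat[alu_only]), -0.3)
  expect_gt(median(kd$de_stat[te_only]), 0.3)
})

test_that("unknown gene ids and unknown effect classes are rejected", {
  sc <- simulate_site_counts(10L, "TE_exon", seed = 1L)
  expect_error(simulate_knockdown_table(sc, beta = c(bogus = 1)), "bogus")
  iso <- toy_isoforms()
  expect_error(simulate_knockdown_table(sc, beta = c(TE_exon = 1),
                                        isoforms = iso), "annotation")
})

test_that("conservation track is elevated at planted nonrepetitive sites", {
  sim <- small_sim()
  track <- simulate_conservation_track(sim)
  ms <- sim$truth$motif_sites
  out <- ms[ms$in_te == FALSE, ]
  site_means <- vapply(seq_len(nrow(out)), function(i)
    mean(track_values(track, out$chrom[i], out$start[i]:out$end[i])),
    numeric(1))
  expect_gt(mean(site_means, na.rm = TRUE), 0.6)  # baseline 0 + delta 1
})
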