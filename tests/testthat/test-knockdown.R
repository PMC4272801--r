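# Binding summaries, class CDF comparisons and the site-class regression.

mk_peaks <- function(genes, classes, regions) {
  data.table::data.table(
    chrom = "chr1", start = seq(100L, by = 200L, length.out = length(genes)),
    end = seq(130L, by = 200L, length.out = length(genes)),
    strand = "+", k = 5, lambda = 1, p_value = 1e-6, q_value = 1e-4,
    gene_id = genes, site_class = classes, region = regions,
    alu = grepl("Alu", classes))
}

test_that("binding summaries count classes and derive exclusive classes", {
  iso <- toy_isoforms()
  pk <- mk_peaks(c("gA", "gA", "gB", "gZ"),
                 c("L1", "L1", "nonrepetitive", "AluY"),
                 c("intron", "intron", "exon", "exon"))
  expect_warning(su <- summarize_binding(pk, iso), regexp = NA)
  expect_equal(attr(su, "n_dropped"), 1L)   # gZ is not annotated
  a <- su[su$gene_id == "gA", ]
  expect_equal(a$TE_intron, 2L)
  expect_equal(a$n_sites, 2L)
  expect_equal(a$exclusive_class, "TE-only")
  b <- su[su$gene_id == "gB", ]
  expect_equal(b$nonrep_exon, 1L)
  expect_equal(b$exclusive_class, "nonrep-only")
})

test_that("alu_split separates Alu sites and mixed genes are mixed", {
  iso <- toy_isoforms()
  pk <- mk_peaks(c("gA", "gA", "gB"),
                 c("AluY", "nonrepetitive", "L2"),
                 c("exon", "intron", "intron"))
  su <- summarize_binding(pk, iso, alu_split = TRUE)
  a <- su[su$gene_id == "gA", ]
  expect_equal(a$Alu_exon, 1L)
  expect_equal(a$nonrep_intron, 1L)
  expect_equal(a$exclusive_class, "mixed")
  b <- su[su$gene_id == "gB", ]
  expect_equal(b$TE_intron, 1L)
  expect_equal(b$exclusive_class, "TE-only")
  # unbound genes complete the partition
  expect_true(all(c("TE-only", "mixed") %in% su$exclusive_class))
  expect_equal(sort(unique(su$exclusive_class)),
               sort(unique(c("TE-only", "mixed", su$exclusive_class))))
})

test_that("exclusive classes partition all genes exhaustively", {
  classes <- c("TE_exon", "TE_intron", "nonrep_exon", "nonrep_intron")
  sc <- simulate_site_counts(500L, classes, seed = 21L)
  # convert counts to a fake peak list via summarize-like reconstruction
  su <- data.table::copy(sc)
  cm <- as.matrix(su[, ..classes])
  su[, n_sites := rowSums(cm)]
  expect_true(all(rowSums(cm) == su$n_sites))
})

test_that("bound vs unbound CDF shift is detected, equal classes are not", {
  classes <- c("TE_intron", "nonrep_intron")
  sc <- simulate_site_counts(2000L, classes, seed = 22L)
  kd <- simulate_knockdown_table(sc, beta = c(TE_intron = 1,
                                              nonrep_intron = 1), seed = 23L)
  cm <- as.matrix(sc[, ..classes])
  su <- data.table::data.table(
    gene_id = sc$gene_id, TE_intron = sc$TE_intron,
    nonrep_intron = sc$nonrep_intron,
    n_sites = rowSums(cm), bound = rowSums(cm) > 0)
  grp <- ifelse(!su$bound, "unbound",
                ifelse(sc$TE_intron > 0 & sc$nonrep_intron == 0, "TE-only",
                       ifelse(sc$nonrep_intron > 0 & sc$TE_intron == 0,
                              "nonrep-only", "mixed")))
  su[, exclusive_class := grp]
  r1 <- compare_class_cdfs(su, kd, "bound", "unbound")
  expect_lt(r1$p_value, 1e-4)
  expect_gt(r1$shift, 0)
  r2 <- compare_class_cdfs(su, kd, "TE-only", "nonrep-only")
  expect_gt(r2$p_value, 0.05)
  # medians increase with site count (binned summary)
  med <- r1$by_count$median
  expect_gt(med[length(med)], med[1])
  # identical classes give p = 1 and shift 0
  r3 <- compare_class_cdfs(su, kd, "bound", "bound")
  expect_equal(r3$shift, 0)
  expect_gt(r3$p_value, 0.99)
  # invariance to row order
  perm <- sample(nrow(su))
  r4 <- compare_class_cdfs(su[perm, ], kd[sample(nrow(kd)), ],
                           "bound", "unbound")
  expect_equal(r4$p_value, r1$p_value)
})

test_that("too-small classes return NA rather than a test", {
  su <- data.table::data.table(
    gene_id = c("g1", "g2"), TE_exon = c(1L, 0L), n_sites = c(1L, 0L),
    bound = c(TRUE, FALSE), exclusive_class = c("TE-only", "unbound"))
  kd <- data.table::data.table(gene_id = c("g1", "g2"), de_stat = c(1, 0),
                               splice_p = c(0.5, 0.5))
  r <- compare_class_cdfs(su, kd, "TE-only", "unbound")
  expect_true(is.na(r$p_value))
})

test_that("regression recovers planted class effects with covering CIs", {
  classes <- c("TE_exon", "TE_intron", "nonrep_exon", "nonrep_intron")
  beta <- c(TE_exon = 1, TE_intron = 1, nonrep_exon = 1, nonrep_intron = 1)
  sc <- simulate_site_counts(2000L, classes, seed = 24L)
  kd <- simulate_knockdown_table(sc, beta = beta, seed = 25L)
  fit <- site_class_regression(sc, kd, classes = classes)
  for (cl in classes) {
    row <- fit[fit$term == cl, ]
    expect_true(row$ci_lo <= 1 && 1 <= row$ci_hi, info = cl)
  }
})

test_that("an opposite-sign Alu effect yields an opposite-sign coefficient", {
  classes <- c("Alu_intron", "TE_intron", "nonrep_intron")
  beta <- c(Alu_intron = -1, TE_intron = 1, nonrep_intron = 1)
  sc <- simulate_site_counts(2000L, classes, seed = 26L)
  kd <- simulate_knockdown_table(sc, beta = beta, seed = 27L)
  fit <- site_class_regression(sc, kd, classes = classes)
  expect_lt(fit[fit$term == "Alu_intron", ]$estimate, -0.5)
  expect_gt(fit[fit$term == "TE_intron", ]$estimate, 0.5)
})

test_that("empty classes are dropped with a warning; all-zero gives intercept only", {
  sc <- data.table::data.table(gene_id = sprintf("g%02d", 1:50),
                               TE_exon = 0L,
                               nonrep_exon = rep(c(0L, 2L), 25))
  kd <- simulate_knockdown_table(sc, beta = c(nonrep_exon = 1), seed = 28L)
  expect_warning(fit <- site_class_regression(sc, kd,
                                              classes = c("TE_exon",
                                                          "nonrep_exon")),
                 "TE_exon")
  expect_true(is.na(fit[fit$term == "TE_exon", ]$estimate))
  expect_false(is.na(fit[fit$term == "nonrep_exon", ]$estimate))
  sc0 <- data.table::copy(sc)[, nonrep_exon := 0L]
  expect_warning(fit0 <- site_class_regression(
    sc0, kd, classes = c("TE_exon", "nonrep_exon")))
  expect_true(all(is.na(fit0[fit0$term != "(Intercept)", ]$estimate)))
})

test_that("splicing analysis detects planted splicing effects at TE sites", {
  classes <- c("TE_intron", "nonrep_intron")
  sc <- simulate_site_counts(2000L, classes, seed = 29L)
  kd <- simulate_knockdown_table(sc, beta = c(TE_intron = 0,
                                              nonrep_intron = 0),
                                 beta_splice = c(TE_intron = 1.5),
                                 seed = 30L)
  cm <- as.matrix(sc[, ..classes])
  su <- data.table::data.table(
    gene_id = sc$gene_id, n_sites = rowSums(cm), bound = rowSums(cm) > 0,
    exclusive_class = ifelse(rowSums(cm) == 0, "unbound",
      ifelse(sc$TE_intron > 0 & sc$nonrep_intron == 0, "TE-only",
             ifelse(sc$nonrep_intron > 0 & sc$TE_intron == 0,
                    "nonrep-only", "mixed"))))
  r <- splicing_class_analysis(su, kd, "TE-only", "unbound")
  expect_lt(r$p_value, 0.01)
  expect_gt(r$shift, 0)
  # no planted effect: uniform splice p-values show no shift
  kd0 <- simulate_knockdown_table(sc, beta = c(TE_intron = 0,
                                               nonrep_intron = 0), seed = 31L)
  r0 <- splicing_class_analysis(su, kd0, "TE-only", "unbound")
  expect_gt(r0$p_value, 0.01)
})
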