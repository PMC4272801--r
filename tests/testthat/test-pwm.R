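# PWM scanning with exact p-values, motif distance, clustering.

test_that("point-mass PWM on uniform background has p = 4^-9 at the top score", {
  pwm <- matrix(0.01 / 3, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["A", ] <- 0.99
  d <- pwm_tail_distribution(pwm)
  expect_equal(pwm_score_pvalue(d, max(d$bins)), 4^-9, tolerance = 1e-12)
  # total mass is one
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  # tail is monotone nonincreasing in the score
  expect_true(all(diff(d$tail) <= 0))
})

test_that("DP tail matches exhaustive enumeration over all 9-mers", {
  # small-scale version (full 4^9 enumeration runs in the acceptance suite)
  set.seed(31)
  for (bg in list(NULL, c(A = 0.4, C = 0.1, G = 0.2, T = 0.3))) {
    pwm <- random_pwm(6L)          # 4^6 = 4096 words
    bgv <- if (is.null(bg)) c(A = .25, C = .25, G = .25, T = .25) else bg
    sb <- pwm_score_bins(pwm, bgv)
    d <- pwm_tail_distribution(pwm, bgv)
    words <- as.matrix(expand.grid(rep(list(1:4), 6)))
    sc <- rowSums(matrix(sb[cbind(as.vector(words),
                                  rep(1:6, each = nrow(words)))],
                         nrow(words)))
    pr <- exp(rowSums(matrix(log(bgv[as.vector(words)]), nrow(words))))
    us <- sort(unique(sc))
    emp <- vapply(us, function(s) sum(pr[sc >= s]), numeric(1))
    expect_lt(max(abs(pwm_score_pvalue(d, us) - emp)), 1e-12)
  }
})

test_that("scanner finds exactly the matching positions of a sharp motif", {
  set.seed(8)
  motif <- "GATTACAGA"
  seqs <- paste0(random_dna(1, 200), motif, random_dna(1, 150), motif,
                 random_dna(1, 100))
  genome <- c(chr1 = seqs)
  iso <- data.table::data.table(
    gene_id = "g1", isoform_id = "g1.t1", chrom = "chr1", strand = "+",
    start = 1L, end = nchar(seqs), feature = "exon", biotype = "mRNA",
    is_pre_rna = FALSE)
  pwm <- matrix(0.01 / 3, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:9) pwm[substr(motif, j, j), j] <- 0.99
  occ <- scan_transcriptome(list(m1 = pwm), genome, iso, NULL)
  expect_equal(sort(occ$start), c(201L, 360L))
  expect_true(all(occ$p_value <= 1e-5))
  expect_true(all(occ$strand == "+"))
})

test_that("minus-strand genes are scanned in RNA sense", {
  set.seed(9)
  motif <- "GATTACAGA"
  left <- random_dna(1, 120)
  genome <- c(chr1 = paste0(left, revcomp(motif), random_dna(1, 120)))
  iso <- data.table::data.table(
    gene_id = "g1", isoform_id = "g1.t1", chrom = "chr1", strand = "-",
    start = 1L, end = nchar(genome[["chr1"]]), feature = "exon",
    biotype = "mRNA", is_pre_rna = FALSE)
  pwm <- matrix(0.01 / 3, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:9) pwm[substr(motif, j, j), j] <- 0.99
  occ <- scan_transcriptome(list(m1 = pwm), genome, iso, NULL)
  expect_equal(occ$start, 121L)
  expect_equal(occ$strand, "-")
})

test_that("occurrence classes follow CDS > 3'UTR > lncRNA > intron precedence", {
  iso <- toy_isoforms()
  cds <- data.table::data.table(
    gene_id = "gA", isoform_id = "gA.t1", chrom = "chr1", strand = "+",
    start = 101L, end = 180L, feature = "CDS", biotype = "mRNA",
    is_pre_rna = FALSE)
  iso2 <- rbind(iso, cds)
  occ <- data.table::data.table(
    chrom = "chr1", start = c(110L, 190L, 1010L, 250L),
    end = c(118L, 198L, 1018L, 258L))
  cls <- retroclip:::classify_positions(
    occ, retroclip:::annotation_class_intervals(iso2))
  expect_equal(cls, c("CDS", "3'UTR", "lncRNA", "intron"))
})

test_that("motif distance is symmetric, zero on identity, sqrt(2) apart on point masses", {
  set.seed(12)
  a <- random_pwm(); b <- random_pwm()
  dab <- motif_distance(a, b); dba <- motif_distance(b, a)
  expect_equal(as.numeric(dab), as.numeric(dba), tolerance = 1e-12)
  expect_gte(as.numeric(dab), 0)
  expect_equal(as.numeric(motif_distance(a, a)), 0)
  pa <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  pa["A", ] <- 1
  pc <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  pc["C", ] <- 1
  expect_equal(as.numeric(motif_distance(pa, pc)), sqrt(2), tolerance = 1e-12)
})

test_that("uniform padding columns carry zero weight in motif distance", {
  # a 3-column informative core shifted by 2 inside uniform padding:
  # distance must be 0 because uniform columns have zero information coverage
  core <- matrix(c(1, 0, 0, 0,  0, 1, 0, 0,  0, 0, 1, 0), 4, 3,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  uni <- matrix(0.25, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  a <- cbind(core, uni, uni)        # core at columns 1-3
  b <- cbind(uni, uni, core)        # core at columns 5-7
  d <- motif_distance(a, b, min_overlap = 3L)
  expect_equal(as.numeric(d), 0, tolerance = 1e-12)
  expect_equal(attr(d, "offset"), 4L)
  # two all-uniform pwms: flagged unweighted distance
  u <- cbind(uni, uni, uni)
  du <- motif_distance(u, u)
  expect_true(attr(du, "flagged"))
  expect_equal(as.numeric(du), 0)
})

test_that("information coverage is 0 for uniform and 1 for point-mass columns", {
  uni <- matrix(0.25, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  pm <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pwm_info_coverage(uni), 0)
  expect_equal(pwm_info_coverage(pm), 1)
})

mk_tesm_set <- function(pwms, enrichment = NULL, support = NULL) {
  n <- length(pwms)
  names(pwms) <- sprintf("t%02d", seq_len(n))
  structure(list(
    meta = data.table::data.table(
      tesm_id = names(pwms), family = "F", orientation = "sense",
      span_start = 1L, span_end = 9L, anchor = 5L,
      support = support %||% rep(1, n),
      enrichment = enrichment %||% seq(n, 1)),
    pwms = pwms), class = "tesm_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical motifs collapse; flatten = 0 keeps every motif", {
  set.seed(14)
  a <- random_pwm(); b <- random_pwm()
  tes <- mk_tesm_set(list(a, a, b), enrichment = c(3, 5, 1))
  reps <- cluster_and_rank(tes, flatten = 0.15)
  expect_equal(nrow(reps$meta), 2L)
  # the duplicated motif's representative is its higher-enrichment member
  expect_true("t02" %in% reps$meta$tesm_id)
  expect_false("t01" %in% reps$meta$tesm_id)
  expect_equal(reps$meta$rank, 1:2)
  all_own <- cluster_and_rank(tes, flatten = 0)
  expect_equal(nrow(all_own$meta), 3L)
  # top_n truncates the ranking
  expect_equal(nrow(cluster_and_rank(tes, flatten = 0, top_n = 2L)$meta), 2L)
  # a single TESM is its own representative
  single <- mk_tesm_set(list(a))
  expect_equal(cluster_and_rank(single)$meta$tesm_id, "t01")
})

test_that("clustering agrees with a brute-force average-linkage oracle", {
  set.seed(15)
  pwms <- replicate(10, random_pwm(), simplify = FALSE)
  # make two tight pairs
  pwms[[2]] <- pwms[[1]]; pwms[[7]] <- pwms[[6]]
  tes <- mk_tesm_set(pwms)
  n <- 10L
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- as.numeric(motif_distance(pwms[[i]], pwms[[j]]))
  # brute-force UPGMA flattened at h
  brute_upgma <- function(D, h) {
    n <- nrow(D); active <- as.list(seq_len(n))
    repeat {
      k <- length(active)
      if (k == 1L) break
      best <- c(Inf, 0, 0)
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        d <- mean(D[active[[i]], active[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
      if (best[1] > h) break
      active[[best[2]]] <- c(active[[best[2]]], active[[best[3]]])
      active[[best[3]]] <- NULL
    }
    grp <- integer(n)
    for (g in seq_along(active)) grp[active[[g]]] <- g
    grp
  }
  want <- brute_upgma(D, 0.15)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  got <- stats::cutree(hc, h = 0.15)
  # same partition up to label permutation
  expect_equal(length(unique(want)), length(unique(got)))
  expect_true(all(tapply(got, want, function(x) length(unique(x))) == 1))
})
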