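# Iterative prefix aligner: brute-force oracle, adapter handling, duplicate
# capping, dataset depth filter.

# brute-force oracle: exact occurrences of every prefix length in genome
# (both strands), replaying the iterative rule literally
brute_prefix_align <- function(read, genome, min_prefix = 20L) {
  hits_at <- function(L) {
    pre <- substr(read, 1L, L)
    out <- list()
    for (cn in names(genome)) {
      s <- genome[[cn]]
      f <- gregexpr(pre, s, fixed = TRUE)[[1]]
      if (f[1] != -1L)
        for (p in as.integer(f))
          out[[length(out) + 1L]] <- list(chrom = cn, strand = "+", a5 = p)
      r <- gregexpr(pre, revcomp(s), fixed = TRUE)[[1]]
      if (r[1] != -1L)
        for (p in as.integer(r))
          out[[length(out) + 1L]] <- list(chrom = cn, strand = "-",
                                          a5 = nchar(s) - p + 1L)
    }
    out
  }
  prev <- hits_at(min_prefix)
  if (length(prev) == 0L) return(NULL)
  if (length(prev) == 1L) return(list(hits = prev, len = min_prefix))
  for (L in seq(min_prefix + 1L, nchar(read))) {
    cur <- hits_at(L)
    if (length(cur) == 0L) return(list(hits = prev, len = L - 1L))
    if (length(cur) == 1L) return(list(hits = cur, len = L))
    prev <- cur
  }
  list(hits = prev, len = nchar(read))
}

test_that("aligner matches a brute-force prefix-occurrence oracle", {
  set.seed(21)
  genome <- c(chr1 = random_dna(1, 3000), chr2 = random_dna(1, 2000))
  # embed a repeated segment to force ambiguity
  seg <- substr(genome[["chr1"]], 501, 560)
  substr(genome[["chr2"]], 1001, 1060) <- seg
  idx <- build_aligner_index(genome)
  reads <- data.table::data.table(
    read_id = sprintf("q%02d", 1:40),
    seq = c(
      # unique genomic reads
      vapply(1:15, function(i) substr(genome[["chr1"]], 30 * i, 30 * i + 35),
             character(1)),
      # reads from the duplicated segment (ambiguous at 20)
      vapply(1:10, function(i) substr(genome[["chr1"]], 498 + i, 498 + i + 35),
             character(1)),
      # reverse-strand reads
      vapply(1:10, function(i)
        revcomp(substr(genome[["chr2"]], 100 * i, 100 * i + 35)), character(1)),
      # adapter-bearing reads: 24 genomic nt + adapter
      vapply(1:4, function(i)
        paste0(substr(genome[["chr1"]], 700 + 50 * i, 723 + 50 * i),
               "TGGAATTCTCGG"), character(1)),
      # pure adapter read
      paste(rep("TGGAATTCTCGGGTGCCAAGG", 2), collapse = "")[1]))
  aln <- align_prefix_iterative(reads, idx)
  for (rid in reads$read_id) {
    got <- aln[aln$read_id == rid, ]
    want <- brute_prefix_align(reads$seq[reads$read_id == rid], genome)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L, info = rid)
    } else {
      expect_equal(nrow(got), length(want$hits), info = rid)
      expect_setequal(anchor5(got$strand, got$blocks),
                      vapply(want$hits, `[[`, integer(1), "a5"))
      expect_equal(unique(got$aligned_len), want$len, info = rid)
    }
  }
  # pure adapter read is discarded
  expect_equal(nrow(aln[aln$read_id == "q40", ]), 0L)
})

test_that("a diverging TE copy resolves multi-reads at the divergence point", {
  set.seed(3)
  base <- random_dna(1, 400)
  copy1 <- base; copy2 <- base; copy3 <- base
  substr(copy1, 26, 26) <- if (substr(base, 26, 26) == "A") "C" else "A"
  genome <- c(chr1 = paste0(random_dna(1, 200), copy1, random_dna(1, 200),
                            copy2, random_dna(1, 200), copy3,
                            random_dna(1, 200)))
  # read from copy1: identical to copies 2,3 up to position 25, diverges at 26
  read <- substr(genome[["chr1"]], 201, 236)
  idx <- build_aligner_index(genome)
  aln <- align_prefix_iterative(
    data.table::data.table(read_id = "r", seq = read), idx)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$pos, 201L)
  expect_gte(aln$aligned_len, 26L)
})

test_that("reads shorter than the seed are skipped and counted", {
  genome <- c(chr1 = random_dna(1, 500))
  idx <- build_aligner_index(genome)
  reads <- data.table::data.table(read_id = c("a", "b"),
                                  seq = c("ACGTACGTACGT",
                                          substr(genome[["chr1"]], 10, 45)))
  aln <- align_prefix_iterative(reads, idx)
  expect_equal(attr(aln, "n_short"), 1L)
  expect_equal(aln$read_id, "b")
})

test_that("placements are capped at max_alignments with weight 1/cap", {
  set.seed(11)
  unit <- random_dna(1, 50)
  genome <- c(chr1 = paste(c(vapply(1:30, function(i) unit, character(1))),
                           collapse = ""))
  idx <- build_aligner_index(genome)
  read <- substr(unit, 1, 36)
  aln <- align_prefix_iterative(
    data.table::data.table(read_id = "m", seq = read), idx,
    max_alignments = 20L)
  expect_equal(nrow(aln), 20L)
  expect_equal(unique(aln$n_alignments), 20L)
  expect_equal(sum(aln$weight), 1)
})

test_that("positional duplicate capping keeps `cap` records deterministically", {
  aln <- retroclip:::make_alignments(
    read_id = c("e", "d", "c", "b", "a", "x", "y"),
    chrom = c(rep("chr1", 5), "chr1", "chr1"),
    strand = c(rep("+", 5), "-", "-"),
    blocks = c(rep("100:30", 5), "100:30", "100:30"))
  capped <- cap_positional_duplicates(aln, cap = 2L)
  plus <- capped[capped$strand == "+", ]
  expect_equal(nrow(plus), 2L)               # 5 at one position -> 2
  expect_equal(sort(plus$read_id), c("a", "b"))  # lexicographic retention
  expect_equal(nrow(capped[capped$strand == "-", ]), 2L)  # 2 at cap stay
  # shuffled input gives the identical retained set
  capped2 <- cap_positional_duplicates(aln[sample(nrow(aln)), ], cap = 2L)
  expect_equal(sort(capped2$read_id), sort(capped$read_id))
})

test_that("dataset depth filter uses distinct reads and an inclusive boundary", {
  mk <- function(n) retroclip:::make_alignments(
    read_id = sprintf("r%06d", seq_len(n)), chrom = "chr1", strand = "+",
    blocks = sprintf("%d:30", seq_len(n)))
  expect_false(filter_dataset_depth(mk(1999), min_reads = 2000L)$pass)
  expect_true(filter_dataset_depth(mk(2000), min_reads = 2000L)$pass)
  empty <- mk(1)[0, ]
  res <- filter_dataset_depth(empty, min_reads = 2000L)
  expect_false(res$pass)
  expect_equal(res$n_reads, 0L)
})

test_that("alignment monotonicity: longer prefixes never gain placements", {
  # grow the prefix of one ambiguous read manually and compare hit counts
  set.seed(13)
  unit <- random_dna(1, 80)
  g <- paste0(unit, random_dna(1, 100), unit, random_dna(1, 100))
  substr(g, 205, 205) <- if (substr(g, 205, 205) == "A") "G" else "A"
  genome <- c(chr1 = g)
  idx <- build_aligner_index(genome)
  read <- substr(g, 1, 40)
  counts <- vapply(20:40, function(L) {
    a <- align_prefix_iterative(
      data.table::data.table(read_id = "r", seq = substr(read, 1, L)), idx)
    nrow(a)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
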