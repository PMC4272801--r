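# Format readers/writers: GTF, RepeatMasker dialect, SAM-like, score tracks.

test_that("GTF coordinates survive a round trip and conventions hold", {
  iso <- toy_isoforms()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(iso, path)
  back <- read_gtf(path)
  expect_setequal(unique(back$isoform_id), unique(iso$isoform_id))
  a <- back[back$isoform_id == "gA.t1" & back$feature == "exon", ]
  expect_equal(a$start, c(101L, 301L, 601L))
  expect_equal(a$end, c(200L, 400L, 700L))
  # reverse-strand exons come back in ascending genomic order
  b <- back[back$isoform_id == "gB.t1", ]
  expect_equal(b$start, c(1001L, 1301L))
  expect_equal(b$strand, c("-", "-"))
  expect_equal(unique(b$biotype), "lncRNA")
})

test_that("GTF single-exon line maps 1-based closed to internal coordinates", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tsrc\texon\t100\t200\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "t1";'), path)
  iso <- read_gtf(path)
  expect_equal(iso$start, 100L)
  expect_equal(iso$end, 200L)
  # internally 1-based closed: width is end - start + 1
  expect_equal(iso$end - iso$start + 1L, 101L)
})

test_that("GTF with overlapping exons in one transcript is rejected", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t100\t200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tsrc\texon\t150\t300\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";')), path)
  expect_error(read_gtf(path), "overlapping")
})

test_that("malformed GTF attributes report the offending line", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t100\t200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    "chr1\tsrc\texon\t300\t400\t.\t+\t.\tno_attributes_here"), path)
  expect_error(read_gtf(path), "line 2")
})

test_that("TE annotation normalises minus-strand consensus columns", {
  # hand-normalised five-record fixture: plus and minus records describing
  # the same consensus spans must load identically
  lines <- c(
    "  SW  perc perc perc  query position in query matching repeat position in repeat",
    "score  div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
    "",
    " 1000  0.0  0.0  0.0 chr1 101 400 (0) + AluX AluX 1 300 (12) 1",
    " 1000  0.0  0.0  0.0 chr1 501 800 (0) C AluX AluX (12) 300 1 2",
    " 1000  0.0  0.0  0.0 chr1 901 1100 (0) + AluX AluX 101 300 (12) 3",
    " 1000  0.0  0.0  0.0 chr1 1201 1400 (0) C AluX AluX (12) 300 101 4",
    " 1000  0.0  0.0  0.0 chr2 101 250 (0) C L1X L1X (0) 900 751 5")
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(lines, path)
  te <- read_te_annotation(path)
  expect_equal(nrow(te), 5L)
  expect_equal(te[te$chrom == "chr1", ]$cons_start, c(1L, 1L, 101L, 101L))
  expect_equal(te[te$chrom == "chr1", ]$cons_end, rep(300L, 4))
  expect_equal(unique(te[te$chrom == "chr1", ]$cons_length), 312L)
  expect_true(all(te$cons_start <= te$cons_end))
  l1 <- te[te$family == "L1X", ]
  expect_equal(l1$cons_start, 751L)
  expect_equal(l1$cons_length, 900L)
})

test_that("TE records with impossible consensus spans are rejected", {
  lines <- c(
    " 1000  0.0  0.0  0.0 chr1 101 400 (0) + AluX AluX 1 300 (12) 1",
    " 1000  0.0  0.0  0.0 chr1 501 900 (0) + AluX AluX 1 400 (12) 2")
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(lines, path)
  # record 2 claims cons_end 400 on a 312-nt consensus
  expect_warning(te <- read_te_annotation(path,
                                          cons_lengths = c(AluX = 312L)),
                 "rejected")
  expect_equal(nrow(te), 1L)
})

test_that("TE annotation loader is idempotent under write/read", {
  sim <- small_sim()
  p1 <- withr::local_tempfile(fileext = ".out")
  p2 <- withr::local_tempfile(fileext = ".out")
  write_te_annotation(sim$te_instances, p1)
  te1 <- read_te_annotation(p1)
  write_te_annotation(te1, p2)
  te2 <- read_te_annotation(p2)
  cols <- c("chrom", "start", "end", "strand", "family",
            "cons_start", "cons_end", "cons_length")
  expect_equal(as.data.frame(te1)[cols], as.data.frame(te2)[cols])
})

test_that("alignment SAM round trip preserves all fields", {
  set.seed(42)
  n <- 100L
  starts <- sample.int(5000L, n)
  blocks <- ifelse(runif(n) < 0.8,
                   sprintf("%d:%d", starts, 30L),
                   sprintf("%d:%d,%d:%d", starts, 12L, starts + 500L, 18L))
  aln <- retroclip:::make_alignments(
    read_id = sprintf("r%03d", seq_len(n)),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    blocks = blocks,
    n_alignments = sample(1:4, n, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".sam")
  write_alignments(aln, path)
  back <- read_alignments(path)
  data.table::setorder(aln, read_id, chrom, pos)
  data.table::setorder(back, read_id, chrom, pos)
  expect_equal(as.data.frame(back), as.data.frame(aln), ignore_attr = TRUE)
})

test_that("NH-less records infer multiplicity; weights sum to one per read", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "r1\t0\tchr1\t100\t255\t20M\t*\t0\t0\t*\t*",
    "r1\t0\tchr1\t900\t255\t20M\t*\t0\t0\t*\t*",
    "r1\t16\tchr2\t50\t255\t20M\t*\t0\t0\t*\t*",
    "r2\t0\tchr1\t10\t255\t20M\t*\t0\t0\t*\t*\tNH:i:4",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), path)
  aln <- read_alignments(path)
  expect_equal(attr(aln, "n_unmapped"), 1L)
  r1 <- aln[aln$read_id == "r1", ]
  expect_equal(unique(r1$n_alignments), 3L)
  expect_equal(sum(r1$weight), 1)
  expect_equal(aln[aln$read_id == "r2", ]$weight, 0.25)
})

test_that("score tracks distinguish missing positions from zero", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t3\t1.5", "chr1\t5\t6\t0"), path)
  tr <- read_score_track(path, c(chr1 = 10L))
  expect_equal(track_values(tr, "chr1", 1:3), rep(1.5, 3))
  expect_true(is.na(track_values(tr, "chr1", 4)))
  expect_equal(track_values(tr, "chr1", 6), 0)
  # round trip
  p2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_score_track(tr, p2)
  tr2 <- read_score_track(p2, c(chr1 = 10L))
  expect_equal(tr2$scores, tr$scores)
})

test_that("genome FASTA flags non-nucleotide letters on load", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTXACGT"), path)
  expect_warning(read_genome_fasta(path), "invalid")
  # empty sequences are rejected outright
  p2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", ""), p2)
  expect_error(suppressWarnings(read_genome_fasta(p2)), "empty")
})
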