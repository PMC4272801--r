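# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small simulation with one planted TE motif and nonrepetitive copies
small_sim_config <- function(seed = 101L) {
  fams <- rbind(
    default_te_families()[c(1, 3, 5)],
    data.table::data.table(name = "AluP", cons_length = 300L, n_copies = 30L,
                           truncation_rate = 0.1, substitution_rate = 0.02))
  simulation_config(
    seed = seed, n_chroms = 2L, chrom_len = 120000L, n_genes = 40L,
    n_reads = 15000L, te_families = fams,
    planted_motifs = data.frame(motif = "ACCGTTAGC", family = "AluP",
                                multiplier = 10, n_nonrep = 25L))
}

small_sim <- function() fixture("small_sim", function() {
  simulate_genome(small_sim_config())
})

small_reads <- function() fixture("small_reads", function() {
  simulate_clip_reads(small_sim())
})

small_index <- function() fixture("small_index", function() {
  sim <- small_sim()
  build_aligner_index(sim$genome, sim$isoforms)
})

small_alignments <- function() fixture("small_alignments", function() {
  align_prefix_iterative(small_reads()$reads, small_index())
})

# a deterministic hand-built exon table: two genes, one on each strand
toy_isoforms <- function() {
  data.table::data.table(
    gene_id = c("gA", "gA", "gA", "gA", "gA", "gB", "gB"),
    isoform_id = c("gA.t1", "gA.t1", "gA.t1", "gA.t2", "gA.t2",
                   "gB.t1", "gB.t1"),
    chrom = "chr1", strand = c(rep("+", 5), "-", "-"),
    start = c(101L, 301L, 601L, 101L, 601L, 1001L, 1301L),
    end = c(200L, 400L, 700L, 200L, 700L, 1100L, 1400L),
    feature = "exon", biotype = c(rep("mRNA", 5), "lncRNA", "lncRNA"),
    is_pre_rna = FALSE)
}

# 5' anchor of alignments / truth records (read base 1 in the genome)
anchor5 <- function(strand, blocks) {
  b <- retroclip:::decode_blocks(blocks)
  lo <- b[, .(s = min(start), e = max(end)), by = row]
  data.table::setorder(lo, row)
  ifelse(strand == "+", lo$s, lo$e)
}

# uniform random column-normalised PWM
random_pwm <- function(w = 9L) {
  m <- matrix(stats::runif(4L * w), 4L, w,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2L, colSums(m), "/")
}
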