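# End-to-end orchestration: simulate -> align -> filter -> abundance/null ->
# enrichment -> motifs -> scan -> peaks -> knockdown, with a JSON run manifest
# for reproducibility and checksum-based stage skipping.

#' Pipeline stage parameters
#'
#' Defaults are the pipeline's canonical constants: 20-nt alignment seed,
#' positional duplicate cap 2, three-fold consensus segmentation, 9-nt motifs,
#' 1e-5 scan p-value, 0.15 cluster flattening, top 300 motifs, 30-nt peak
#' windows and a 200,000-read minimum dataset depth.
#'
#' @param min_prefix aligner seed length.
#' @param dup_cap positional duplicate cap.
#' @param fold consensus segmentation ratio threshold.
#' @param scan_p motif scan p-value threshold.
#' @param flatten cluster flattening height.
#' @param top_n motif representatives retained.
#' @param window,step,alpha peak-caller window geometry and q threshold.
#' @param min_reads minimum distinct aligned reads per dataset.
#' @param kd_beta named class effects used for the synthetic knockdown table.
#' @return list of stage parameters.
#' @export
pipeline_params <- function(min_prefix = 20L, dup_cap = 2L, fold = 3,
                            scan_p = 1e-5, flatten = 0.15, top_n = 300L,
                            window = 30L, step = 5L, alpha = 0.01,
                            min_reads = 200000L,
                            kd_beta = c(TE_exon = 1, TE_intron = 1,
                                        nonrep_exon = 1, nonrep_intron = 1)) {
  list(min_prefix = as.integer(min_prefix), dup_cap = as.integer(dup_cap),
       fold = fold, scan_p = scan_p, flatten = flatten,
       top_n = as.integer(top_n), window = as.integer(window),
       step = as.integer(step), alpha = alpha,
       min_reads = as.integer(min_reads), kd_beta = kd_beta)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `simulation` and `params` override the defaults of
#' [simulation_config()] and [pipeline_params()] respectively.
#'
#' @param path YAML file.
#' @return list with `config` (a `retroclip_config`) and `params`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulation %||% list()
  if (!is.null(sim$te_families))
    sim$te_families <- data.table::rbindlist(sim$te_families)
  if (!is.null(sim$planted_motifs))
    sim$planted_motifs <- data.table::rbindlist(sim$planted_motifs)
  if (!is.null(sim$family_enrichment))
    sim$family_enrichment <- unlist(sim$family_enrichment)
  cfg <- do.call(simulation_config, sim)
  prm <- do.call(pipeline_params, y$params %||% list())
  list(config = cfg, params = prm)
}

# ---- plain-text writers for stage outputs -------------------------------

#' Write peaks as BED6+ (k, lambda, q_value, gene_id, site_class, region)
#' @param peaks peak table from [call_peaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  dt <- data.table::as.data.table(peaks)
  score <- pmin(1000L, as.integer(round(-10 * log10(
    pmax(dt$q_value, 1e-100)))))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%.6g\t%.6g\t%.6g\t%s\t%s\t%s",
                   dt$chrom, dt$start - 1L, dt$end, dt$gene_id, score,
                   dt$strand, dt$k, dt$lambda, dt$q_value, dt$gene_id,
                   dt$site_class, dt$region)
  writeLines(lines, path)
  invisible(path)
}

#' Write motif occurrences as BED6 (score = -log10 p)
#' @param occ occurrence table from [scan_transcriptome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occ, path) {
  dt <- data.table::as.data.table(occ)
  lines <- sprintf("%s\t%d\t%d\t%s\t%.3f\t%s\t%s\t%d",
                   dt$chrom, dt$start - 1L, dt$end, dt$tesm_id,
                   -log10(pmax(dt$p_value, 1e-300)), dt$strand,
                   dt$class, as.integer(dt$in_repeat))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tesm_set as metadata TSV plus MEME-minimal PWM file
#' @param tesms a `tesm_set`.
#' @param meta_path metadata TSV path.
#' @param pwm_path MEME-minimal motif file path.
#' @return `meta_path`, invisibly.
#' @export
write_tesms <- function(tesms, meta_path, pwm_path) {
  meta <- data.table::copy(tesms$meta)
  if (nrow(meta))
    meta[, consensus := vapply(tesms$pwms[tesm_id], pwm_consensus,
                               character(1))]
  data.table::fwrite(meta, meta_path, sep = "\t")
  con <- file(pwm_path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (id in meta$tesm_id) {
    p <- tesms$pwms[[id]]
    writeLines(c(sprintf("MOTIF %s", id),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         ncol(p))), con)
    writeLines(apply(t(p), 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(meta_path)
}

# ---- manifest helpers ---------------------------------------------------

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = FALSE)
  else list(stages = list())
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, manifest_path(out_dir), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

params_fingerprint <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

file_md5 <- function(paths) unname(tools::md5sum(paths))

# TRUE when the stage can be skipped: same fingerprint, all outputs intact.
# Outputs that exist but no longer match their recorded checksum indicate
# corruption (the parameters did not change), which is a hard error naming
# the file.
stage_skippable <- function(manifest, name, fingerprint) {
  st <- manifest$stages[[name]]
  if (is.null(st)) return(FALSE)
  if (!identical(st$fingerprint, fingerprint)) return(FALSE)
  outs <- names(st$outputs)
  if (!length(outs) || !all(file.exists(outs))) return(FALSE)
  want <- unname(vapply(st$outputs, as.character, character(1)))
  got <- unname(file_md5(outs))
  bad <- which(want != got)
  if (length(bad))
    stopf("checksum mismatch for intermediate file '%s'", outs[bad[1]])
  TRUE
}

# verify input files against the checksums recorded when they were produced
verify_inputs <- function(manifest, paths) {
  recorded <- list()
  for (st in manifest$stages)
    for (f in names(st$outputs)) recorded[[f]] <- st$outputs[[f]]
  for (p in paths) {
    if (!is.null(recorded[[p]]) &&
        !identical(as.character(recorded[[p]]), unname(file_md5(p))))
      stopf("checksum mismatch for intermediate file '%s'", p)
  }
  invisible(TRUE)
}

record_stage <- function(manifest, name, fingerprint, outputs, info = list()) {
  manifest$stages[[name]] <- list(
    fingerprint = fingerprint,
    outputs = as.list(stats::setNames(file_md5(outputs), outputs)),
    info = info)
  manifest
}

# ---- the pipeline -------------------------------------------------------

#' Run the full pipeline on a synthetic dataset
#'
#' Executes simulate, align, filter, abundance, enrich, motifs, scan, peaks
#' and knockdown in dependency order, writing plain-text outputs and a JSON
#' manifest (parameter fingerprints plus md5 checksums of every output) into
#' `out_dir`. A stage is skipped when its parameter fingerprint matches the
#' existing manifest and its outputs are intact; a corrupted intermediate file
#' raises a checksum error naming the file. With the same configuration and
#' seed, two runs produce byte-identical outputs.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param params stage parameters from [pipeline_params()].
#' @param families families to profile for motifs; default all simulated
#'   families.
#' @return list with the paths of all outputs and the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, params = pipeline_params(),
                         families = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- read_manifest(out_dir)
  pth <- function(...) file.path(out_dir, ...)
  res <- list(paths = list())

  # -- stage: simulate ----------------------------------------------------
  fp <- params_fingerprint(list(stage = "simulate",
                                config = unclass(config)[
                                  setdiff(names(config), "te_families")],
                                te = as.data.frame(config$te_families),
                                pm = as.data.frame(config$planted_motifs),
                                kd_beta = params$kd_beta))
  sim_files <- pth(c("genome.fa", "consensi.fa", "annotation.gtf", "te.out",
                     "reads.fq", "conservation.bedGraph", "read_truth.tsv",
                     "motif_sites.tsv", "knockdown_stats.tsv"))
  names(sim_files) <- c("genome", "consensi", "gtf", "te", "reads", "cons",
                        "read_truth", "motif_sites", "kd")
  if (!stage_skippable(manifest, "simulate", fp)) {
    message("[retroclip] stage simulate")
    sim <- simulate_genome(config)
    rd <- simulate_clip_reads(sim)
    track <- simulate_conservation_track(sim)
    write_genome_fasta(sim$genome, sim_files["genome"])
    write_genome_fasta(sim$consensi, sim_files["consensi"])
    write_gtf(sim$isoforms, sim_files["gtf"])
    write_te_annotation(sim$te_instances, sim_files["te"])
    write_fastq(rd$reads, sim_files["reads"])
    write_score_track(track, sim_files["cons"])
    data.table::fwrite(rd$truth, sim_files["read_truth"], sep = "\t")
    data.table::fwrite(sim$truth$motif_sites, sim_files["motif_sites"],
                       sep = "\t")
    kd <- simulate_knockdown_table(
      true_site_counts(sim), beta = params$kd_beta,
      seed = config$seed + 3L, isoforms = sim$isoforms)
    data.table::fwrite(kd, sim_files["kd"], sep = "\t")
    manifest <- record_stage(manifest, "simulate", fp, sim_files,
                             list(n_reads = nrow(rd$reads)))
    write_manifest(manifest, out_dir)
  } else message("[retroclip] stage simulate: up to date, skipped")
  res$paths$simulate <- sim_files

  genome <- read_genome_fasta(sim_files["genome"])
  isoforms <- read_gtf(sim_files["gtf"])
  te <- read_te_annotation(sim_files["te"])
  .idx <- NULL
  get_idx <- function() {
    if (is.null(.idx))
      .idx <<- build_aligner_index(genome, isoforms,
                                   min_prefix = params$min_prefix)
    .idx
  }

  # -- stage: align -------------------------------------------------------
  fp <- params_fingerprint(list(stage = "align", sim = manifest$stages$simulate$fingerprint,
                                min_prefix = params$min_prefix))
  aln_file <- pth("alignments.sam")
  if (!stage_skippable(manifest, "align", fp)) {
    message("[retroclip] stage align")
    verify_inputs(manifest, sim_files[c("genome", "gtf", "reads")])
    reads <- read_fastq(sim_files["reads"])
    aln <- align_prefix_iterative(reads, get_idx(), seed = config$seed)
    write_alignments(aln, aln_file)
    manifest <- record_stage(manifest, "align", fp, aln_file,
                             list(n_alignments = nrow(aln),
                                  n_unaligned = attr(aln, "n_unaligned")))
    write_manifest(manifest, out_dir)
  } else message("[retroclip] stage align: up to date, skipped")
  res$paths$align <- aln_file

  # -- stage: filter ------------------------------------------------------
  fp <- params_fingerprint(list(stage = "filter",
                                align = manifest$stages$align$fingerprint,
                                dup_cap = params$dup_cap,
                                min_reads = params$min_reads))
  cap_file <- pth("alignments.capped.sam")
  if (!stage_skippable(manifest, "filter", fp)) {
    message("[retroclip] stage filter")
    verify_inputs(manifest, aln_file)
    aln <- read_alignments(aln_file)
    capped <- cap_positional_duplicates(aln, cap = params$dup_cap)
    depth <- filter_dataset_depth(capped, min_reads = params$min_reads)
    if (!depth$pass)
      warnf("dataset below the %d-read depth threshold (%d reads)",
            params$min_reads, depth$n_reads)
    write_alignments(capped, cap_file)
    manifest <- record_stage(manifest, "filter", fp, cap_file,
                             list(depth_pass = depth$pass,
                                  n_reads = depth$n_reads))
    write_manifest(manifest, out_dir)
  } else message("[retroclip] stage filter: up to date, skipped")
  res$paths$filter <- cap_file

  capped <- read_alignments(cap_file)
  iso_aug <- augment_pre_rna(isoforms)

  # -- stage: abundance (+ null simulation) -------------------------------
  fp <- params_fingerprint(list(stage = "abundance",
                                filter = manifest$stages$filter$fingerprint))
  ab_file <- pth("abundance.tsv"); null_file <- pth("null.sam")
  if (!stage_skippable(manifest, "abundance", fp)) {
    message("[retroclip] stage abundance")
    verify_inputs(manifest, cap_file)
    model <- estimate_abundances(capped, iso_aug)
    data.table::fwrite(model$isoforms, ab_file, sep = "\t")
    null <- simulate_null_mapped(model, iso_aug, genome, get_idx(),
                                 n_reads = length(unique(capped$read_id)),
                                 seed = config$seed + 11L,
                                 read_len = config$read_len,
                                 cap = params$dup_cap)
    write_alignments(null, null_file)
    manifest <- record_stage(manifest, "abundance", fp,
                             c(ab_file, null_file),
                             list(library_size = model$library_size))
    write_manifest(manifest, out_dir)
  } else message("[retroclip] stage abundance: up to date, skipped")
  res$paths$abundance <- c(ab_file, null_file)

  model <- abundance_model_from_tsv(ab_file)
  null <- read_alignments(null_file)

  # -- stage: enrich ------------------------------------------------------
  fp <- params_fingerprint(list(stage = "enrich",
                                abundance = manifest$stages$abundance$fingerprint))
  enr_file <- pth("enrichment.tsv")
  if (!stage_skippable(manifest, "enrich", fp)) {
    message("[retroclip] stage enrich")
    verify_inputs(manifest, c(cap_file, null_file))
    enr <- compute_enrichment(capped, null, te, isoforms)
    enr <- test_enrichment_significance(enr)
    data.table::fwrite(enr, enr_file, sep = "\t")
    manifest <- record_stage(manifest, "enrich", fp, enr_file)
    write_manifest(manifest, out_dir)
  } else message("[retroclip] stage enrich: up to date, skipped")
  res$paths$enrich <- enr_file

  # -- stage: motifs ------------------------------------------------------
  families <- families %||% unique(te$family)
  fp <- params_fingerprint(list(stage = "motifs",
                                abundance = manifest$stages$abundance$fingerprint,
                                fold = params$fold, families = families))
  prof_file <- pth("consensus_profiles.tsv")
  tesm_meta <- pth("tesms.tsv"); tesm_pwm <- pth("tesms_meme.txt")
  if (!stage_skippable(manifest, "motifs", fp)) {
    message("[retroclip] stage motifs")
    verify_inputs(manifest, c(cap_file, null_file))
    profs <- list(); sets <- list()
    for (fam in families) for (ori in c("sense", "antisense")) {
      prof <- build_consensus_profile(capped, null, te, fam, ori)
      profs[[length(profs) + 1L]] <- data.table::data.table(
        family = fam, orientation = ori,
        cons_pos = seq_len(prof$cons_length),
        clip_cov = prof$clip_cov, null_cov = prof$null_cov,
        norm_ratio = prof$norm_ratio)
      sets[[length(sets) + 1L]] <-
        segment_tesms(prof, capped, te, genome, fold = params$fold)
    }
    data.table::fwrite(data.table::rbindlist(profs), prof_file, sep = "\t")
    tesms <- combine_tesms(sets)
    write_tesms(tesms, tesm_meta, tesm_pwm)
    manifest <- record_stage(manifest, "motifs", fp,
                             c(prof_file, tesm_meta, tesm_pwm),
                             list(n_tesms = nrow(tesms$meta)))
    write_manifest(manifest, out_dir)
    res$tesms <- tesms
  } else {
    message("[retroclip] stage motifs: up to date, skipped")
    res$tesms <- read_tesms(tesm_meta, tesm_pwm)
  }
  res$paths$motifs <- c(prof_file, tesm_meta, tesm_pwm)

  # -- stage: scan (cluster + transcriptome scan) -------------------------
  fp <- params_fingerprint(list(stage = "scan",
                                motifs = manifest$stages$motifs$fingerprint,
                                flatten = params$flatten, top_n = params$top_n,
                                scan_p = params$scan_p))
  occ_file <- pth("occurrences.bed"); rep_file <- pth("tesms_top.tsv")
  if (!stage_skippable(manifest, "scan", fp)) {
    message("[retroclip] stage scan")
    verify_inputs(manifest, c(tesm_meta, tesm_pwm))
    reps <- cluster_and_rank(res$tesms, flatten = params$flatten,
                             top_n = params$top_n)
    rep_meta <- data.table::copy(reps$meta)
    if (nrow(rep_meta))
      rep_meta[, consensus := vapply(reps$pwms[tesm_id], pwm_consensus,
                                     character(1))]
    data.table::fwrite(rep_meta, rep_file, sep = "\t")
    occ <- scan_transcriptome(reps, genome, isoforms, te,
                              p_max = params$scan_p)
    write_occurrences_bed(occ, occ_file)
    manifest <- record_stage(manifest, "scan", fp, c(rep_file, occ_file),
                             list(n_occurrences = nrow(occ)))
    write_manifest(manifest, out_dir)
  } else message("[retroclip] stage scan: up to date, skipped")
  res$paths$scan <- c(rep_file, occ_file)

  # -- stage: peaks -------------------------------------------------------
  fp <- params_fingerprint(list(stage = "peaks",
                                abundance = manifest$stages$abundance$fingerprint,
                                window = params$window, step = params$step,
                                alpha = params$alpha))
  peak_file <- pth("peaks.bed")
  if (!stage_skippable(manifest, "peaks", fp)) {
    message("[retroclip] stage peaks")
    verify_inputs(manifest, c(cap_file, ab_file))
    mp <- build_mappability_track(genome, k = params$min_prefix)
    pk <- call_peaks(capped, iso_aug, model, te, mp,
                     alpha = params$alpha, window = params$window,
                     step = params$step)
    write_peaks_bed(pk, peak_file)
    manifest <- record_stage(manifest, "peaks", fp, peak_file,
                             list(n_peaks = nrow(pk)))
    write_manifest(manifest, out_dir)
  } else message("[retroclip] stage peaks: up to date, skipped")
  res$paths$peaks <- peak_file

  # -- stage: knockdown ---------------------------------------------------
  fp <- params_fingerprint(list(stage = "knockdown",
                                peaks = manifest$stages$peaks$fingerprint,
                                sim = manifest$stages$simulate$fingerprint))
  kd_sum <- pth("binding_summary.tsv"); kd_reg <- pth("regression.tsv")
  if (!stage_skippable(manifest, "knockdown", fp)) {
    message("[retroclip] stage knockdown")
    verify_inputs(manifest, c(peak_file, sim_files[["kd"]]))
    pk <- read_peaks_bed(peak_file)
    stats_tab <- data.table::fread(sim_files[["kd"]])
    su <- summarize_binding(pk, isoforms)
    data.table::fwrite(su, kd_sum, sep = "\t")
    reg <- site_class_regression(su, stats_tab)
    data.table::fwrite(reg, kd_reg, sep = "\t")
    manifest <- record_stage(manifest, "knockdown", fp, c(kd_sum, kd_reg))
    write_manifest(manifest, out_dir)
  } else message("[retroclip] stage knockdown: up to date, skipped")
  res$paths$knockdown <- c(kd_sum, kd_reg)

  res$manifest <- read_manifest(out_dir)
  invisible(res)
}

# true per-gene binding-site counts by class from the simulation truth
true_site_counts <- function(sim) {
  iso <- data.table::as.data.table(sim$isoforms)
  genes <- unique(iso$gene_id)
  ms <- data.table::as.data.table(sim$truth$motif_sites)
  out <- data.table::data.table(gene_id = genes)
  for (cl in c("TE_exon", "TE_intron", "nonrep_exon", "nonrep_intron"))
    out[, (cl) := 0L]
  if (nrow(ms)) {
    splex <- iso[feature == "exon" & is_pre_rna == FALSE,
                 .(chrom, start, end)]
    data.table::setkey(splex, chrom, start, end)
    q <- ms[, .(chrom, start, end, qi = .I)]
    data.table::setkey(q, chrom, start, end)
    hit <- data.table::foverlaps(q, splex, type = "any", nomatch = NULL)
    exonic <- seq_len(nrow(ms)) %in% hit$qi
    ms[, cls := paste(data.table::fifelse(in_te, "TE", "nonrep"),
                      data.table::fifelse(exonic, "exon", "intron"),
                      sep = "_")]
    cnt <- ms[, .N, by = .(gene_id, cls)]
    for (cl in unique(cnt$cls)) {
      m <- cnt[cls == cl]
      out[m, on = "gene_id", (cl) := m$N]
    }
  }
  out[]
}

# read back an abundance TSV as an abundance_model
abundance_model_from_tsv <- function(path) {
  dt <- data.table::fread(path)
  structure(list(isoforms = dt, library_size = sum(dt$mass)),
            class = "abundance_model")
}

#' Read peaks written by [write_peaks_bed()]
#' @param path BED6+ file.
#' @return peak table.
#' @export
read_peaks_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
    col.names = c("chrom", "start0", "end", "name", "score", "strand",
                  "k", "lambda", "q_value", "gene_id", "site_class",
                  "region"))
  dt[, start := start0 + 1L]
  dt[, alu := grepl("Alu", site_class)]
  dt[, .(chrom, start, end, strand, k, lambda, q_value, gene_id,
         site_class, region, alu)]
}

# read back a tesm_set written by write_tesms()
read_tesms <- function(meta_path, pwm_path) {
  meta <- data.table::fread(meta_path)
  lines <- readLines(pwm_path)
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF ")) {
      id <- sub("^MOTIF ", "", lines[i])
      w <- as.integer(sub(".* w= *([0-9]+).*", "\\1", lines[i + 1L]))
      rows <- lines[(i + 2L):(i + 1L + w)]
      m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x), numeric(4)))
      pwm <- t(m)
      rownames(pwm) <- c("A", "C", "G", "T")
      pwms[[id]] <- pwm
      i <- i + 2L + w
    } else i <- i + 1L
  }
  if ("consensus" %in% names(meta)) meta[, consensus := NULL]
  structure(list(meta = meta, pwms = pwms), class = "tesm_set")
}
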