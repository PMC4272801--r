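# FASTA / FASTQ I/O (thin wrappers over Biostrings)

#' Read a genome (or TE consensus) FASTA file
#'
#' Sequences are uppercased and checked against the A/C/G/T/N alphabet.
#'
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  freq <- Biostrings::alphabetFrequency(x)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0))
    stopf("sequence '%s' contains letters outside {A,C,G,T,N}",
          names(x)[which(extra > 0)[1]])
  if (any(Biostrings::width(x) == 0L)) stopf("empty sequence in %s", path)
  x
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTQ file of reads
#'
#' @param path FASTQ file.
#' @return data.table with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table::data.table(read_id = sub("\\s.*$", "", names(x)),
                         seq = as.character(x))
}

#' Write reads to FASTQ
#'
#' All bases get the constant quality 'I'.
#'
#' @param reads data.frame with `read_id` and `seq`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}
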