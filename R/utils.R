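# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals (downsampling, null simulation) do not
#' perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  y <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(y, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Random DNA sequences
#'
#' Uniform i.i.d. A/C/G/T strings; uses the current RNG stream.
#'
#' @param n number of sequences.
#' @param len length of each sequence (recycled).
#' @return character vector.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# split equal-length strings into an n x len character matrix
str_to_mat <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0))
  matrix(unlist(strsplit(x, "", fixed = TRUE)), nrow = length(x), byrow = TRUE)
}

# per-position characters of a single long string as a char vector
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 2-bit numeric codes of every k-mer of one long string (A=0..T=3); exact in
# doubles for k <= 25. NA where the window contains a non-ACGT letter.
encode_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(NULL)
  c0 <- match(str_chars(s), c("A", "C", "G", "T")) - 1
  m <- n - k + 1L
  codes <- numeric(m)
  for (j in seq_len(k))
    codes <- codes + c0[j:(j + m - 1L)] * 4^(k - j)
  codes
}

# 2-bit codes of equal-length short strings (one code per string)
encode_words <- function(x, k) {
  if (!length(x)) return(numeric(0))
  mt <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)),
                     c("A", "C", "G", "T")) - 1,
               nrow = length(x), byrow = TRUE)
  as.numeric(mt %*% 4^((k - 1):0))
}

# deterministic small integer hash of a string (for per-read tie breaking)
str_hash <- function(x) {
  vapply(x, function(s) {
    v <- utf8ToInt(s)
    as.integer(sum(v * seq_along(v)) %% 2147483647L)
  }, integer(1), USE.NAMES = FALSE)
}

# collapse genomic blocks to the "start:len,start:len" encoding
encode_blocks <- function(starts, lens) {
  paste(sprintf("%d:%d", starts, lens), collapse = ",")
}

# expand the "start:len,..." encoding; returns data.table(start, end)
decode_blocks <- function(blocks) {
  if (length(blocks) == 0L) {
    return(data.table::data.table(row = integer(0), start = integer(0),
                                  end = integer(0)))
  }
  parts <- strsplit(blocks, ",", fixed = TRUE)
  n <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  sl <- matrix(as.integer(unlist(strsplit(flat, ":", fixed = TRUE))),
               ncol = 2, byrow = TRUE)
  data.table::data.table(
    row = rep(seq_along(blocks), n),
    start = sl[, 1],
    end = sl[, 1] + sl[, 2] - 1L
  )
}
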