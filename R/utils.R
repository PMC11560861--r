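# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA strings
#'
#' Draws `n` independent sequences of length `width` uniformly over
#' {A,C,G,T}. Used for clone tags, cell barcodes, UMIs and read stuffers.
#'
#' @param n number of sequences.
#' @param width sequence length in bases.
#' @return character vector of length `n`.
#' @keywords internal
rand_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Unique random DNA strings; resamples on collision (collisions are
# vanishingly rare at width 20 but uniqueness is an invariant downstream).
rand_dna_unique <- function(n, width) {
  out <- rand_dna(n, width)
  while (anyDuplicated(out)) {
    dup <- duplicated(out)
    out[dup] <- rand_dna(sum(dup), width)
  }
  out
}

# Phred scores (offset 33) for a single quality string.
qual_to_phred <- function(qual) {
  if (is.na(qual) || !nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Apply per-base substitution errors at rate `rate` to each string in
# `seqs`; returns list(seq = mutated strings, n_errors = per-string count).
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) {
    return(list(seq = seqs, n_errors = integer(length(seqs))))
  }
  n_err <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (j in hit) {
      ch[j] <- sample(setdiff(DNA_BASES, ch[j]), 1L)
    }
    n_err[i] <- length(hit)
    if (length(hit)) seqs[i] <- paste(ch, collapse = "")
  }
  list(seq = seqs, n_errors = n_err)
}

# stopifnot-style check with a formatted message.
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}

# TSV conventions used for all tabular exchange: header, tab-separated,
# no quoting, literal "NA" for missing.
read_tsv_strict <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_strict <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop(sprintf("cannot write '%s': %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}
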