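# FASTQ input/output for the paired-read layout used by droplet
# single-cell libraries: Read1 = 20-base cell barcode + 10-base UMI,
# Read2 = cDNA carrying the clone-barcode cassette.

# Strip pairing suffixes ("/1", "/2") and space-delimited comments from a
# FASTQ id line (without the leading "@").
strip_read_id <- function(id) {
  sub("/[12]$", "", sub("[ \t].*$", "", id))
}

read_fastq_records <- function(path) {
  assert_that(file.exists(path), "FASTQ file not found: %s", path)
  lines <- readLines(path)  # base connections decompress .gz transparently
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record in '%s' starting at line %d",
                 path, 4L * (n %/% 4L) + 1L), call. = FALSE)
  }
  idx <- seq(1L, n, by = 4L)
  ids <- lines[idx]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ header in '%s' at line %d",
                 path, idx[bad[1L]]), call. = FALSE)
  }
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  badlen <- which(nchar(seqs) != nchar(quals))
  if (length(badlen)) {
    stop(sprintf("sequence/quality length mismatch in '%s' at line %d",
                 path, idx[badlen[1L]] + 1L), call. = FALSE)
  }
  badseq <- which(!grepl("^[ACGTN]*$", seqs))
  if (length(badseq)) {
    stop(sprintf("non-ACGTN base in '%s' at line %d",
                 path, idx[badseq[1L]] + 1L), call. = FALSE)
  }
  data.frame(read_id = strip_read_id(substring(ids, 2L)),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Read paired FASTQ files
#'
#' Streams two FASTQ files (plain or gzip, detected by content) into a
#' table of read pairs in file order. Read ids are matched pairwise after
#' stripping "/1"/"/2" suffixes and space-delimited comments; any
#' divergence is a hard error.
#'
#' @param path_r1,path_r2 FASTQ files for Read1 and Read2.
#' @return data.frame with columns `read_id`, `read1_seq`, `read1_qual`,
#'   `read2_seq`, `read2_qual`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq_records(path_r1)
  r2 <- read_fastq_records(path_r2)
  if (nrow(r1) != nrow(r2)) {
    k <- min(nrow(r1), nrow(r2)) + 1L
    longer <- if (nrow(r1) > nrow(r2)) r1 else r2
    stop(sprintf(
      "record count mismatch: %d reads in '%s' vs %d in '%s'; first unpaired record is '%s' (record %d)",
      nrow(r1), path_r1, nrow(r2), path_r2, longer$read_id[k], k),
      call. = FALSE)
  }
  div <- which(r1$read_id != r2$read_id)
  if (length(div)) {
    stop(sprintf("read id mismatch at record %d: '%s' vs '%s'",
                 div[1L], r1$read_id[div[1L]], r2$read_id[div[1L]]),
         call. = FALSE)
  }
  data.frame(read_id = r1$read_id,
             read1_seq = r1$seq, read1_qual = r1$qual,
             read2_seq = r2$seq, read2_qual = r2$qual,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param read_id,seq,qual parallel character vectors.
#' @param path output path; a ".gz" suffix selects gzip compression.
#' @export
write_fastq <- function(read_id, seq, qual, path) {
  assert_that(length(read_id) == length(seq) && length(seq) == length(qual),
              "read_id, seq and qual must have equal length")
  lines <- character(4L * length(read_id))
  if (length(read_id)) {
    lines[seq(1L, length(lines), 4L)] <- paste0("@", read_id)
    lines[seq(2L, length(lines), 4L)] <- seq
    lines[seq(3L, length(lines), 4L)] <- "+"
    lines[seq(4L, length(lines), 4L)] <- qual
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
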