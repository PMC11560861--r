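# Clone-tag capture from cDNA reads: locate the N-base random tag between
# two fixed anchor sequences, tolerate anchor substitutions, quality-filter
# the tag, collapse UMIs, and assign clone barcodes to cells.

CAPTURE_STATUSES <- c("captured", "no_anchor", "bad_length",
                      "low_quality", "ambiguous")

# Mismatch counts of `anchor` placed at each `start` within the
# corresponding `seqs` string (equal-width windows, ungapped Hamming).
.anchor_mismatches <- function(windows, anchor) {
  a <- utf8ToInt(anchor)
  vapply(windows, function(w) sum(utf8ToInt(w) != a), 0L, USE.NAMES = FALSE)
}

# Enumerate in-bounds placements of `anchor` in every sequence with at most
# `k` substitutions. Returns list(starts = list of int vectors, mm = list of
# mismatch counts), parallel to `seqs`.
.scan_anchor <- function(subjects, seqs, widths, anchor, k) {
  hits <- Biostrings::vmatchPattern(anchor, subjects, max.mismatch = k)
  starts <- Biostrings::startIndex(hits)
  w <- nchar(anchor)
  n <- length(seqs)
  out_starts <- vector("list", n)
  out_mm <- vector("list", n)
  # flatten hits for one vectorized window extraction
  lens <- vapply(starts, function(s) if (is.null(s)) 0L else length(s), 0L)
  if (sum(lens) > 0L) {
    read_idx <- rep.int(seq_len(n), lens)
    st <- unlist(starts[lens > 0L], use.names = FALSE)
    inb <- st >= 1L & (st + w - 1L) <= widths[read_idx]
    read_idx <- read_idx[inb]
    st <- st[inb]
    if (length(st)) {
      mm <- .anchor_mismatches(substr(seqs[read_idx], st, st + w - 1L), anchor)
      sp <- split(seq_along(st), read_idx)
      for (key in names(sp)) {
        i <- as.integer(key)
        j <- sp[[key]]
        out_starts[[i]] <- st[j]
        out_mm[[i]] <- mm[j]
      }
    }
  }
  list(starts = out_starts, mm = out_mm)
}

# Vectorized tag location over many reads. Returns data.frame(clone_tag,
# status). See locate_tag() for the per-read contract.
locate_tags <- function(seqs, quals, spec) {
  validate_construct(spec)
  n <- length(seqs)
  status <- rep("no_anchor", n)
  tag <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.frame(clone_tag = tag, status = status,
                      stringsAsFactors = FALSE))
  }
  subjects <- Biostrings::DNAStringSet(seqs)
  widths <- nchar(seqs)
  k <- spec$max_anchor_mismatches
  up <- .scan_anchor(subjects, seqs, widths, spec$upstream_anchor, k)
  dn <- .scan_anchor(subjects, seqs, widths, spec$downstream_anchor, k)
  w_up <- nchar(spec$upstream_anchor)
  tl <- spec$tag_length

  for (i in seq_len(n)) {
    us <- up$starts[[i]]
    ds <- dn$starts[[i]]
    if (is.null(us) || is.null(ds) || !length(us) || !length(ds)) next
    ue <- us + w_up - 1L
    # gap between upstream end and downstream start must equal tag_length
    gap <- outer(ds, ue, FUN = "-") - 1L          # rows: down, cols: up
    ok <- which(gap == tl, arr.ind = TRUE)
    if (!nrow(ok)) {
      status[i] <- "bad_length"
      next
    }
    total <- dn$mm[[i]][ok[, 1L]] + up$mm[[i]][ok[, 2L]]
    best <- which(total == min(total))
    tag_starts <- ue[ok[best, 2L]] + 1L
    cand <- substr(rep.int(seqs[i], length(best)), tag_starts,
                   tag_starts + tl - 1L)
    if (length(unique(cand)) > 1L) {
      status[i] <- "ambiguous"
      next
    }
    t1 <- cand[1L]
    s1 <- tag_starts[1L]
    if (grepl("N", t1, fixed = TRUE)) {
      status[i] <- "low_quality"
      next
    }
    pq <- utf8ToInt(substr(quals[i], s1, s1 + tl - 1L)) - 33L
    if (any(pq < spec$min_tag_qual)) {
      status[i] <- "low_quality"
      next
    }
    status[i] <- "captured"
    tag[i] <- t1
  }
  data.frame(clone_tag = tag, status = status, stringsAsFactors = FALSE)
}

#' Locate the clone tag in a cDNA read
#'
#' Finds the best ungapped placements of the construct's upstream and
#' downstream anchors (Hamming distance, every offset, at most
#' `max_anchor_mismatches` substitutions each) and extracts the tag between
#' them. The gap between the anchors must equal `tag_length`. Rejections are
#' reported as statuses, never errors:
#'
#' * `no_anchor` — one or both anchors have no placement within tolerance;
#' * `bad_length` — anchors found but never at tag-length spacing;
#' * `ambiguous` — two placements tie on total mismatches but yield
#'   different tags;
#' * `low_quality` — tag contains N or a base below `min_tag_qual`;
#' * `captured` — tag accepted.
#'
#' @param read2_seq cDNA sequence (character scalar).
#' @param read2_qual matching Phred+33 quality string.
#' @param spec a [construct_spec()].
#' @return list with `clone_tag` (NA unless captured) and `status`.
#' @export
locate_tag <- function(read2_seq, read2_qual, spec) {
  res <- locate_tags(read2_seq, read2_qual, spec)
  list(clone_tag = res$clone_tag[1L], status = res$status[1L])
}

#' Capture clone tags from a table of read pairs
#'
#' Applies [locate_tag()] to every read pair, takes the cell barcode and
#' UMI from fixed Read1 positions (bases 1-20 and 21-30), and aggregates
#' captured reads into barcode calls with read support.
#'
#' @param pairs data.frame from [read_fastq_pairs()].
#' @param spec a [construct_spec()].
#' @return list with `calls` (data.frame `cell_id`, `umi`, `clone_tag`,
#'   `read_support`, one row per distinct triple) and `stats` (named counts
#'   per capture status plus `reads_seen`).
#' @export
capture_reads <- function(pairs, spec) {
  assert_that(all(nchar(pairs$read1_seq) >= 30L) || nrow(pairs) == 0L,
              "Read1 must carry at least 30 bases (20 cell barcode + 10 UMI)")
  loc <- locate_tags(pairs$read2_seq, pairs$read2_qual, spec)
  stats <- as.list(table(factor(loc$status, levels = CAPTURE_STATUSES)))
  stats <- c(list(reads_seen = nrow(pairs)), lapply(stats, as.integer))
  keep <- loc$status == "captured"
  if (!any(keep)) {
    calls <- data.frame(cell_id = character(0), umi = character(0),
                        clone_tag = character(0), read_support = integer(0),
                        stringsAsFactors = FALSE)
    return(list(calls = calls, stats = stats))
  }
  cell <- substr(pairs$read1_seq[keep], 1L, 20L)
  umi <- substr(pairs$read1_seq[keep], 21L, 30L)
  key <- paste(cell, umi, loc$clone_tag[keep], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  calls <- data.frame(cell_id = vapply(parts, `[`, "", 1L),
                      umi = vapply(parts, `[`, "", 2L),
                      clone_tag = vapply(parts, `[`, "", 3L),
                      read_support = as.integer(tab),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, stats = stats)
}

# Collapse one (cell, tag) group of UMIs. Processes UMIs in descending
# original-support order (ties lexicographic); a UMI merges into the kept
# UMI of strictly greater accumulated support at Hamming distance 1 (the
# most supported such UMI, ties lexicographic). Returns named support vector.
.collapse_umi_group <- function(umis, support) {
  ord <- order(-support, umis)
  umis <- umis[ord]
  support <- support[ord]
  ints <- lapply(umis, utf8ToInt)
  kept <- integer(0)            # indices into umis
  acc <- numeric(0)             # accumulated support, parallel to kept
  for (j in seq_along(umis)) {
    d1 <- which(vapply(kept, function(kk) {
      sum(ints[[j]] != ints[[kk]]) == 1L
    }, logical(1L)) & acc > support[j])
    if (length(d1)) {
      tgt <- d1[order(-acc[d1], umis[kept[d1]])][1L]
      acc[tgt] <- acc[tgt] + support[j]
    } else {
      kept <- c(kept, j)
      acc <- c(acc, support[j])
    }
  }
  stats::setNames(as.integer(acc), umis[kept])
}

#' Collapse sequencing-error UMIs
#'
#' Within each (cell, clone tag) group, UMIs one mismatch away from a more
#' supported UMI are corrected to it, so one molecule is not counted twice
#' because of a sequencing error in the UMI. Total read support is conserved.
#'
#' @param calls data.frame of captured calls (`cell_id`, `umi`, `clone_tag`,
#'   `read_support`) as from [capture_reads()].
#' @return calls data.frame with corrected UMIs (same columns).
#' @export
correct_umis <- function(calls) {
  if (!nrow(calls)) return(calls)
  grp <- paste(calls$cell_id, calls$clone_tag, sep = "\r")
  idx <- split(seq_len(nrow(calls)), grp)
  out <- vector("list", length(idx))
  for (g in seq_along(idx)) {
    i <- idx[[g]]
    if (length(i) == 1L) {
      out[[g]] <- calls[i, , drop = FALSE]
      next
    }
    merged <- .collapse_umi_group(calls$umi[i], calls$read_support[i])
    out[[g]] <- data.frame(cell_id = calls$cell_id[i[1L]],
                           umi = names(merged),
                           clone_tag = calls$clone_tag[i[1L]],
                           read_support = as.integer(merged),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign clone tags to cells
#'
#' After UMI collapse, a clone tag is retained in a cell when it is
#' supported by at least `min_umi_support` distinct UMIs.
#'
#' @param calls UMI-collapsed calls from [correct_umis()].
#' @param spec a [construct_spec()] (supplies `min_umi_support`).
#' @return data.frame `cell_id`, `clone_tag`, `n_umis`, `n_reads` with one
#'   row per retained (cell, tag).
#' @export
assign_cells <- function(calls, spec) {
  validate_construct(spec)
  if (!nrow(calls)) {
    return(data.frame(cell_id = character(0), clone_tag = character(0),
                      n_umis = integer(0), n_reads = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(calls$cell_id, calls$clone_tag, sep = "\r")
  n_umis <- tapply(calls$umi, key, function(u) length(unique(u)))
  n_reads <- tapply(calls$read_support, key, sum)
  parts <- strsplit(names(n_umis), "\r", fixed = TRUE)
  df <- data.frame(cell_id = vapply(parts, `[`, "", 1L),
                   clone_tag = vapply(parts, `[`, "", 2L),
                   n_umis = as.integer(n_umis),
                   n_reads = as.integer(n_reads),
                   stringsAsFactors = FALSE)
  df <- df[df$n_umis >= spec$min_umi_support, , drop = FALSE]
  df <- df[order(df$cell_id, df$clone_tag), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Resolve cells carrying multiple clone barcodes
#'
#' Cells with one tag keep it; cells with two or three tags are merged into
#' a composite clone id (the "+"-join of the lexicographically sorted tags),
#' which is treated as an ordinary clone id downstream; cells with four or
#' more tags are dropped as untraceable.
#'
#' @param assigned data.frame from [assign_cells()] (`cell_id`, `clone_tag`,
#'   optionally `n_umis`).
#' @return data.frame with one row per cell: `cell_id`, `n_tags`,
#'   `clone_tags` ("+"-joined sorted tags), `merged_clone_id` (NA when
#'   dropped), `umi_support` ("tag=count" pairs, ";"-joined), `resolution`
#'   in {single, merged, dropped}.
#' @export
resolve_multibarcode <- function(assigned) {
  if (!nrow(assigned)) {
    return(data.frame(cell_id = character(0), n_tags = integer(0),
                      clone_tags = character(0),
                      merged_clone_id = character(0),
                      umi_support = character(0), resolution = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(assigned$n_umis)) assigned$n_umis <- NA_integer_
  idx <- split(seq_len(nrow(assigned)), assigned$cell_id)
  cell_id <- names(idx)
  n_tags <- integer(length(idx))
  clone_tags <- character(length(idx))
  merged <- character(length(idx))
  support <- character(length(idx))
  resolution <- character(length(idx))
  for (g in seq_along(idx)) {
    i <- idx[[g]]
    o <- order(assigned$clone_tag[i])
    tags <- assigned$clone_tag[i][o]
    n <- length(tags)
    n_tags[g] <- n
    clone_tags[g] <- paste(tags, collapse = "+")
    support[g] <- paste(tags, assigned$n_umis[i][o], sep = "=",
                        collapse = ";")
    if (n >= 4L) {
      merged[g] <- NA_character_
      resolution[g] <- "dropped"
    } else {
      merged[g] <- clone_tags[g]
      resolution[g] <- if (n == 1L) "single" else "merged"
    }
  }
  df <- data.frame(cell_id = cell_id, n_tags = n_tags,
                   clone_tags = clone_tags, merged_clone_id = merged,
                   umi_support = support, resolution = resolution,
                   stringsAsFactors = FALSE)
  df <- df[order(df$cell_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
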