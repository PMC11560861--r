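# Independent oracles and fixture builders used across the suite.
# The locate oracle is a direct Hamming scan over every offset, written
# without Biostrings so it cannot share a defect with the implementation.

oracle_locate <- function(seq, qual, spec) {
  k <- spec$max_anchor_mismatches
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  scan <- function(anchor) {
    a <- strsplit(anchor, "", fixed = TRUE)[[1]]
    w <- length(a)
    n <- length(chars)
    if (n < w) return(list(starts = integer(0), mm = integer(0)))
    starts <- seq_len(n - w + 1L)
    idx <- outer(starts, 0:(w - 1L), "+")
    M <- matrix(chars[idx], nrow = length(starts))
    mm <- rowSums(M != matrix(a, nrow = length(starts), ncol = w,
                              byrow = TRUE))
    keep <- mm <= k
    list(starts = starts[keep], mm = as.integer(mm[keep]))
  }
  up <- scan(spec$upstream_anchor)
  dn <- scan(spec$downstream_anchor)
  if (!length(up$starts) || !length(dn$starts)) {
    return(list(clone_tag = NA_character_, status = "no_anchor"))
  }
  w_up <- nchar(spec$upstream_anchor)
  tl <- spec$tag_length
  best_mm <- Inf
  best_tags <- character(0)
  best_starts <- integer(0)
  for (iu in seq_along(up$starts)) {
    for (id in seq_along(dn$starts)) {
      ue <- up$starts[iu] + w_up - 1L
      if (dn$starts[id] - ue - 1L != tl) next
      tot <- up$mm[iu] + dn$mm[id]
      tag <- substr(seq, ue + 1L, ue + tl)
      if (tot < best_mm) {
        best_mm <- tot
        best_tags <- tag
        best_starts <- ue + 1L
      } else if (tot == best_mm) {
        best_tags <- c(best_tags, tag)
        best_starts <- c(best_starts, ue + 1L)
      }
    }
  }
  if (!length(best_tags)) {
    return(list(clone_tag = NA_character_, status = "bad_length"))
  }
  if (length(unique(best_tags)) > 1L) {
    return(list(clone_tag = NA_character_, status = "ambiguous"))
  }
  tag <- best_tags[1L]
  s <- best_starts[1L]
  if (grepl("N", tag, fixed = TRUE)) {
    return(list(clone_tag = NA_character_, status = "low_quality"))
  }
  pq <- utf8ToInt(substr(qual, s, s + tl - 1L)) - 33L
  if (any(pq < spec$min_tag_qual)) {
    return(list(clone_tag = NA_character_, status = "low_quality"))
  }
  list(clone_tag = tag, status = "captured")
}

# Brute-force tally of a cells table into clone/compartment counts,
# written with plain subsetting loops (independent of build_fate_table).
oracle_tally <- function(cells, lineages) {
  if (is.null(cells$qc_pass)) cells$qc_pass <- TRUE
  cells <- cells[cells$qc_pass, ]
  clones <- sort(unique(stats::na.omit(cells$merged_clone_id)))
  hspc <- sapply(clones, function(cl) {
    sum(!is.na(cells$merged_clone_id) & cells$merged_clone_id == cl &
          cells$lineage == "HSPC")
  })
  mat <- sapply(lineages, function(l) {
    sapply(clones, function(cl) {
      sum(!is.na(cells$merged_clone_id) & cells$merged_clone_id == cl &
            cells$lineage == l)
    })
  })
  if (length(clones) == 1L) mat <- matrix(mat, nrow = 1L,
                                          dimnames = list(clones, lineages))
  list(clones = clones,
       hspc = as.integer(hspc),
       mat = mat,
       n_hspc_total = sum(cells$lineage == "HSPC"),
       lineage_totals = sapply(lineages,
                               function(l) sum(cells$lineage == l)),
       n_downstream_total = sum(cells$lineage != "HSPC"))
}

# Attach the observed clone id of each simulated cell to its annotation row.
sim_cells <- function(sim) {
  cells <- sim$annotation
  cells$merged_clone_id <-
    sim$resolved$merged_clone_id[match(cells$cell_id, sim$resolved$cell_id)]
  cells
}

# Build a cells data.frame from explicit per-clone counts: `hspc` is a
# named vector of clone HSPC counts, `down` a clone x lineage matrix,
# totals give compartment sizes (remainder becomes unbarcoded background,
# spread over lineages as evenly as possible).
cells_from_counts <- function(hspc, down, n_hspc_total, lineage_totals) {
  lineages <- colnames(down)
  rows <- list()
  add <- function(clone, lineage, n) {
    if (n > 0) rows[[length(rows) + 1L]] <<- data.frame(
      merged_clone_id = rep(clone, n), lineage = rep(lineage, n),
      stringsAsFactors = FALSE)
  }
  for (cl in names(hspc)) add(cl, "HSPC", hspc[[cl]])
  add(NA_character_, "HSPC", n_hspc_total - sum(hspc))
  for (cl in rownames(down)) {
    for (l in lineages) add(cl, l, down[cl, l])
  }
  for (l in lineages) {
    add(NA_character_, l, lineage_totals[[l]] - sum(down[, l]))
  }
  df <- do.call(rbind, rows)
  df$cell_id <- sprintf("c%05d", seq_len(nrow(df)))
  df$qc_pass <- TRUE
  df
}

toy_spec <- function(...) {
  construct_spec("ACGTACGTACGTAGCA", "TTGGCCAATTGGCCTA", ...)
}

# A clean Read2 carrying the cassette at a given offset, padded to `len`.
make_read2 <- function(tag, spec, offset = 10L, len = 100L,
                       pad_char = "A") {
  cassette <- paste0(spec$upstream_anchor, tag, spec$downstream_anchor)
  right <- len - offset - nchar(cassette)
  stopifnot(right >= 0L)
  paste0(strrep(pad_char, offset), cassette, strrep(pad_char, right))
}

substitute_base <- function(seq, pos, base) {
  paste0(substr(seq, 1L, pos - 1L), base,
         substr(seq, pos + 1L, nchar(seq)))
}

q40 <- function(n) strrep("I", n)
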