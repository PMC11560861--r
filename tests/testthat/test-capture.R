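spec <- toy_spec()
TAG <- "GATTACAGATTACAGGCCTT"

test_that("an exact cassette is captured with its tag at any offset", {
  for (off in c(0L, 10L, 48L)) {
    r2 <- make_read2(TAG, spec, offset = off)
    res <- locate_tag(r2, q40(nchar(r2)), spec)
    expect_equal(res$status, "captured")
    expect_equal(res$clone_tag, TAG)
  }
})

test_that("anchor mismatch tolerance is exactly max_anchor_mismatches", {
  r2 <- make_read2(TAG, spec, offset = 10L)
  one_err <- substitute_base(r2, 11L, "T")   # inside upstream anchor (A->T)
  res <- locate_tag(one_err, q40(100L), spec)
  expect_equal(res$status, "captured")
  expect_equal(res$clone_tag, TAG)
  expect_equal(oracle_locate(one_err, q40(100L), spec)$status, "captured")

  two_err <- substitute_base(one_err, 13L, "A")  # G->A, second substitution
  res2 <- locate_tag(two_err, q40(100L), spec)
  expect_equal(res2$status, "no_anchor")
  expect_equal(oracle_locate(two_err, q40(100L), spec)$status, "no_anchor")
})

test_that("a wrong-length gap between anchors is rejected as bad_length", {
  short_tag <- substr(TAG, 1, 19)
  r2 <- paste0(strrep("A", 10), spec$upstream_anchor, short_tag,
               spec$downstream_anchor, strrep("A", 39))
  expect_equal(locate_tag(r2, q40(nchar(r2)), spec)$status, "bad_length")
})

test_that("tag N content and low quality bases demote captures", {
  r2 <- make_read2("GATTACAGATTACAGGCCTN", spec)
  expect_equal(locate_tag(r2, q40(100L), spec)$status, "low_quality")

  r2 <- make_read2(TAG, spec, offset = 10L)
  qual <- q40(100L)
  # one tag base (position 10+16+5 within read) below Phred 20
  substr(qual, 31L, 31L) <- "+"   # Phred 10
  expect_equal(locate_tag(r2, qual, spec)$status, "low_quality")
  # low quality outside the tag does not matter
  qual2 <- q40(100L)
  substr(qual2, 1L, 5L) <- "!!!!!"
  expect_equal(locate_tag(r2, qual2, spec)$status, "captured")
})

test_that("tied best placements with different tags are ambiguous", {
  tag2 <- "CCCCCGGGGGAAAAATTTTT"
  r2 <- paste0(spec$upstream_anchor, TAG, spec$downstream_anchor,
               spec$upstream_anchor, tag2, spec$downstream_anchor)
  res <- locate_tag(r2, q40(nchar(r2)), spec)
  expect_equal(res$status, "ambiguous")
  expect_equal(oracle_locate(r2, q40(nchar(r2)), spec)$status, "ambiguous")
})

test_that("capture is position-invariant under random padding", {
  set.seed(42)
  for (i in 1:25) {
    off <- sample(0:48, 1)
    pad <- clonefate:::rand_dna(2, 60)
    cassette <- paste0(spec$upstream_anchor, TAG, spec$downstream_anchor)
    r2 <- paste0(substr(pad[1], 1, off), cassette,
                 substr(pad[2], 1, 48 - off))
    res <- locate_tag(r2, q40(nchar(r2)), spec)
    o <- oracle_locate(r2, q40(nchar(r2)), spec)
    expect_equal(res$status, o$status)
    if (res$status == "captured") expect_equal(res$clone_tag, TAG)
  }
})

test_that("statuses and tags match the brute-force scanner on noisy reads", {
  cfg <- sim_config(seed = 31, n_clones = 12,
                    construct = spec,
                    error_rates = list(anchor = 0.04, tag = 0.02))
  sim <- simulate_clones(cfg)
  r1 <- tempfile(); r2 <- tempfile()
  manifest <- emit_reads(sim, r1, r2)
  pairs <- read_fastq_pairs(r1, r2)
  n <- min(nrow(pairs), 400L)
  got <- clonefate:::locate_tags(pairs$read2_seq[1:n],
                                 pairs$read2_qual[1:n], spec)
  for (i in seq_len(n)) {
    o <- oracle_locate(pairs$read2_seq[i], pairs$read2_qual[i], spec)
    expect_identical(got$status[i], o$status)
    expect_identical(got$clone_tag[i], o$clone_tag)
  }
})

test_that("UMI correction merges 1-mismatch minor UMIs and conserves reads", {
  calls <- data.frame(cell_id = "cell1", clone_tag = TAG,
                      umi = c("AAAAAAAAAA", "AAAAAAAAAT"),
                      read_support = c(5L, 1L), stringsAsFactors = FALSE)
  out <- correct_umis(calls)
  expect_equal(nrow(out), 1L)
  expect_equal(out$umi, "AAAAAAAAAA")
  expect_equal(out$read_support, 6L)

  far <- data.frame(cell_id = "cell1", clone_tag = TAG,
                    umi = c("AAAAAAAAAA", "TTTTTTTTTT"),
                    read_support = c(3L, 3L), stringsAsFactors = FALSE)
  expect_equal(nrow(correct_umis(far)), 2L)

  tie <- data.frame(cell_id = "cell1", clone_tag = TAG,
                    umi = c("AAAAAAAAAA", "AAAAAAAAAT"),
                    read_support = c(3L, 3L), stringsAsFactors = FALSE)
  expect_equal(nrow(correct_umis(tie)), 2L)  # equal support never merges
})

test_that("UMI correction conserves support and never adds UMIs (property)", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    umis <- clonefate:::rand_dna(n, 10)
    # force some near-duplicates
    if (n > 2) umis[2] <- substitute_base(umis[1], sample(10, 1), "A")
    calls <- data.frame(cell_id = "c", clone_tag = "t", umi = umis,
                        read_support = sample(1:9, n, replace = TRUE),
                        stringsAsFactors = FALSE)
    calls <- aggregate(read_support ~ cell_id + clone_tag + umi, calls, sum)
    out <- correct_umis(calls)
    expect_equal(sum(out$read_support), sum(calls$read_support))
    expect_lte(nrow(out), nrow(calls))
    expect_true(all(out$umi %in% calls$umi))
  }
})

test_that("cells keep tags only at sufficient distinct-UMI support", {
  calls <- data.frame(
    cell_id = c("c1", "c1", "c1", "c2"),
    clone_tag = c("tagA", "tagA", "tagA", "tagB"),
    umi = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "AAAAAAAAAA"),
    read_support = c(1L, 2L, 1L, 1L), stringsAsFactors = FALSE)
  a1 <- assign_cells(calls, toy_spec(min_umi_support = 1L))
  expect_equal(a1$n_umis[a1$cell_id == "c1"], 3L)
  a2 <- assign_cells(calls, toy_spec(min_umi_support = 2L))
  expect_equal(a2$cell_id, "c1")   # c2's single-UMI tag dropped
})

test_that("multi-barcode cells resolve by the 1/2-3/4+ rule", {
  assigned <- data.frame(
    cell_id = c("s", "m", "m", "t", "t", "t", "d", "d", "d", "d"),
    clone_tag = c("A", "B", "A", "C", "A", "B", "A", "B", "C", "D"),
    n_umis = 1L, stringsAsFactors = FALSE)
  res <- resolve_multibarcode(assigned)
  res <- res[match(c("s", "m", "t", "d"), res$cell_id), ]
  expect_equal(res$resolution, c("single", "merged", "merged", "dropped"))
  expect_equal(res$merged_clone_id, c("A", "A+B", "A+B+C", NA))
  expect_equal(res$n_tags, c(1L, 2L, 3L, 4L))
})

test_that("multi-barcode resolution is idempotent", {
  assigned <- data.frame(
    cell_id = c("m", "m", "s", "d", "d", "d", "d"),
    clone_tag = c("B", "A", "Z", "A", "B", "C", "D"),
    n_umis = 1L, stringsAsFactors = FALSE)
  once <- resolve_multibarcode(assigned)
  # feed the resolved tag sets back through
  back <- do.call(rbind, lapply(seq_len(nrow(once)), function(i) {
    data.frame(cell_id = once$cell_id[i],
               clone_tag = strsplit(once$clone_tags[i], "+",
                                    fixed = TRUE)[[1]],
               n_umis = 1L, stringsAsFactors = FALSE)
  }))
  twice <- resolve_multibarcode(back)
  expect_equal(twice[, c("cell_id", "n_tags", "clone_tags",
                         "merged_clone_id", "resolution")],
               once[, c("cell_id", "n_tags", "clone_tags",
                        "merged_clone_id", "resolution")])
})

test_that("noise-free end-to-end capture recovers the simulated map exactly", {
  cfg <- sim_config(seed = 13, n_clones = 20, construct = spec)
  sim <- simulate_clones(cfg)
  r1 <- tempfile(); r2 <- tempfile()
  emit_reads(sim, r1, r2)
  pairs <- read_fastq_pairs(r1, r2)
  cap <- capture_reads(pairs, spec)
  expect_equal(cap$stats$captured, cap$stats$reads_seen)
  resolved <- resolve_multibarcode(
    assign_cells(correct_umis(cap$calls), spec))
  truth <- sim$resolved[order(sim$resolved$cell_id), ]
  expect_equal(resolved$cell_id, truth$cell_id)
  expect_equal(resolved$merged_clone_id, truth$merged_clone_id)
  expect_true(all(resolved$resolution == "single"))
})
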