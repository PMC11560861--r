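LIN <- default_lineages()

# small handmade universe: 50 HSPCs (clone X has 5), 200 downstream
# (clone X has 30: 10 B + 20 T), clone Y lives only in HSPCs
toy_cells <- function() {
  down <- matrix(0L, nrow = 2, ncol = 9, dimnames = list(c("X", "Y"), LIN))
  down["X", "B"] <- 10L
  down["X", "T"] <- 20L
  cells_from_counts(hspc = c(X = 5L, Y = 3L), down = down,
                    n_hspc_total = 50L,
                    lineage_totals = setNames(c(100L, 40L, rep(8L, 6), 12L),
                                              LIN))
}

test_that("fate table tallies clones against full compartment totals", {
  cells <- toy_cells()
  tab <- build_fate_table(cells, LIN)
  expect_equal(tab$n_hspc_total, 50L)
  expect_equal(tab$n_downstream_total, 200L)
  expect_equal(tab$hspc_counts[["X"]], 5L)
  expect_equal(sum(tab$lineage_counts["X", ]), 30L)
  expect_equal(tab$lineage_counts["Y", "B"], 0L)
  # unbarcoded cells count in totals, not in any clone
  expect_equal(sum(tab$hspc_counts), 8L)
  o <- oracle_tally(cells, LIN)
  expect_equal(unname(tab$hspc_counts), o$hspc)
  expect_equal(unname(tab$lineage_totals), unname(o$lineage_totals))
  expect_error(build_fate_table(
    data.frame(cell_id = "z", merged_clone_id = NA, lineage = "Weird")),
    "unknown lineage")
})

test_that("fate table equals a brute-force tally on simulated data", {
  sim <- simulate_clones(sim_config(seed = 21, n_clones = 25,
                                    detection_dropout = 0.1))
  cells <- sim_cells(sim)
  tab <- build_fate_table(cells, LIN)
  o <- oracle_tally(cells, LIN)
  expect_equal(tab$clone_ids, o$clones)
  expect_equal(unname(tab$hspc_counts), o$hspc)
  expect_equal(unname(tab$lineage_counts), unname(o$mat))
  expect_equal(tab$n_hspc_total, o$n_hspc_total)
  expect_equal(tab$n_downstream_total, o$n_downstream_total)
})

test_that("output value is the ratio of compartment shares", {
  tab <- build_fate_table(toy_cells(), LIN)
  ov <- output_value("X", tab)
  expect_equal(ov$O1, 30 / 200)
  expect_equal(ov$O2, 5 / 50)
  expect_equal(ov$output_value, 1.5)
  expect_equal(ov$output_class, "unclassified")  # 1.5 sits in the gap
  # clone absent downstream: value 0, class low
  ovY <- output_value("Y", tab)
  expect_equal(ovY$O1, 0)
  expect_equal(ovY$output_value, 0)
  expect_equal(ovY$output_class, "low")
})

test_that("output value requires an HSPC clone", {
  down <- matrix(0L, 1, 9, dimnames = list("Z", LIN))
  down["Z", "B"] <- 4L
  cells <- cells_from_counts(hspc = c(Z = 0L), down = down,
                             n_hspc_total = 10L,
                             lineage_totals = setNames(rep(10L, 9), LIN))
  tab <- build_fate_table(cells, LIN)
  expect_error(output_value("Z", tab), "not an HSPC clone")
  expect_error(m_value("Z", tab), "not an HSPC clone")
})

test_that("output classification uses strict thresholds with gaps", {
  values <- c(0, 0.39, 0.4, 0.8, 1.0, 1.2, 2.0, 2.5)
  expect_equal(classify_output(values),
               c("low", "low", "unclassified", "unclassified", "med",
                 "unclassified", "unclassified", "high"))
  expect_error(classify_output(-0.1), "non-negative")
  # a value of exactly 2.0 sits on the boundary: O1=40/100, O2=2/10
  expect_equal(classify_output((40 / 100) / (2 / 10)), "unclassified")
})

test_that("M-value counts seeded downstream lineages and maps to potency", {
  down <- matrix(0L, 3, 9, dimnames = list(c("all", "three", "none"), LIN))
  down["all", ] <- 2L
  down["three", c("B", "T", "NK")] <- 1L
  cells <- cells_from_counts(hspc = c(all = 2L, three = 2L, none = 2L),
                             down = down, n_hspc_total = 20L,
                             lineage_totals = setNames(rep(10L, 9), LIN))
  tab <- build_fate_table(cells, LIN)
  expect_equal(m_value("all", tab)$m_value, 9L)
  expect_equal(m_value("all", tab)$potency_class, "pluripotent")
  expect_equal(m_value("three", tab)$potency_class, "multipotent")
  expect_equal(m_value("none", tab)$m_value, 0L)
  expect_equal(m_value("none", tab)$potency_class, "none")
  expect_equal(potency_class(1L, 9L), "unipotent")
  expect_equal(potency_class(8L, 9L), "multipotent")
})

test_that("output_value is zero exactly when m_value is zero", {
  sim <- simulate_clones(sim_config(seed = 33, n_clones = 40,
                                    detection_dropout = 0.3))
  tab <- build_fate_table(sim_cells(sim), LIN)
  res <- compute_fate_results(tab)
  expect_equal(res$output_value == 0, res$m_value == 0)
})

test_that("bias score is within-lineage share over overall share", {
  down <- matrix(0L, 1, 9, dimnames = list("X", LIN))
  down["X", "B"] <- 20L
  down["X", "T"] <- 30L
  cells <- cells_from_counts(
    hspc = c(X = 2L), down = down, n_hspc_total = 10L,
    lineage_totals = setNames(c(100L, rep(112L, 7), 116L), LIN))
  tab <- build_fate_table(cells, LIN)   # 1000 downstream cells
  b <- bias_score("X", "B", tab)
  expect_equal(b$D1, 20 / 100)
  expect_equal(b$D2, 50 / 1000)
  expect_equal(b$score, 4.0)
  expect_equal(bias_score("X", "NK", tab)$score, 0)  # absent lineage
  expect_error(bias_score("X", "nope", tab), "not in fate table")
})

test_that("a proportionally distributed clone scores 1 in every lineage", {
  totals <- setNames(c(100L, 200L, 50L, 150L, 100L, 100L, 100L, 100L,
                       100L), LIN)
  down <- matrix(as.integer(totals / 10), 1, 9,
                 dimnames = list("P", LIN))
  cells <- cells_from_counts(hspc = c(P = 2L), down = down,
                             n_hspc_total = 10L, lineage_totals = totals)
  tab <- build_fate_table(cells, LIN)
  for (l in LIN) expect_equal(bias_score("P", l, tab)$score, 1.0)
})

test_that("bias scores satisfy the weighted normalization identity", {
  sim <- simulate_clones(sim_config(seed = 17, n_clones = 30))
  tab <- build_fate_table(sim_cells(sim), LIN)
  scores <- bias_matrix(tab)
  w <- tab$lineage_totals / tab$n_downstream_total
  for (cl in tab$clone_ids) {
    if (all(is.na(scores[cl, ]))) next
    expect_equal(sum(scores[cl, ] * w), 1, tolerance = 1e-12)
  }
  # D2 == 0 is an error for the scalar accessor
  hspc_only <- tab$clone_ids[rowSums(tab$lineage_counts) == 0]
  if (length(hspc_only)) {
    expect_error(bias_score(hspc_only[1], "B", tab), "absent downstream")
  }
})

test_that("dropout never raises O1 or M (monotonicity)", {
  sim <- simulate_clones(sim_config(seed = 23, n_clones = 15))
  cells <- sim_cells(sim)
  tab <- build_fate_table(cells, LIN)
  res <- compute_fate_results(tab)
  # remove downstream cells of each clone at random
  set.seed(1)
  drop <- !is.na(cells$merged_clone_id) & cells$lineage != "HSPC" &
    runif(nrow(cells)) < 0.4
  cells2 <- cells
  cells2$merged_clone_id[drop] <- NA
  res2 <- compute_fate_results(build_fate_table(cells2, LIN))
  m <- merge(res, res2, by = "clone_tag", suffixes = c("", ".drop"))
  expect_true(all(m$O1.drop <= m$O1))
  expect_true(all(m$m_value.drop <= m$m_value))
})

test_that("lymphoid/myeloid bias calls follow group-aggregated scores", {
  groups <- default_lineage_groups()
  down <- matrix(0L, 2, 9, dimnames = list(c("lym", "prop"), LIN))
  down["lym", c("B", "T", "NK")] <- c(40L, 40L, 40L)
  totals <- setNames(rep(100L, 9), LIN)
  down["prop", ] <- 10L
  cells <- cells_from_counts(hspc = c(lym = 2L, prop = 2L), down = down,
                             n_hspc_total = 10L, lineage_totals = totals)
  tab <- build_fate_table(cells, LIN)
  calls <- call_bias(tab, groups, threshold = 2, min_clone_cells = 10L)
  expect_equal(calls$bias_label[calls$clone_id == "lym"], "lymphoid")
  expect_equal(calls$bias_label[calls$clone_id == "prop"], "none")
  # lymphoid-only clone: group score = downstream total / lymphoid total
  expect_equal(calls$lymphoid_score[calls$clone_id == "lym"], 900 / 300)
  # small clones are never called
  calls2 <- call_bias(tab, groups, threshold = 2, min_clone_cells = 500L)
  expect_true(all(calls2$bias_label == "none"))
  expect_error(call_bias(tab, list(lymphoid = c("B"), myeloid = c("T"))),
               "not assigned")
})

test_that("PL-HSPC labels require pluripotency and low/med output", {
  out <- data.frame(clone_id = c("a", "b", "c", "d"),
                    output_class = c("low", "high", "med", "med"))
  pot <- data.frame(clone_id = c("a", "b", "c", "d"),
                    potency_class = c("pluripotent", "pluripotent",
                                      "pluripotent", "multipotent"))
  expect_equal(label_pl_hspcs(out, pot), c("a", "c"))
  expect_error(label_pl_hspcs(out[1:2, ], pot), "same clones")
})

test_that("transduction summary counts barcoded fractions and bias", {
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:100),
    merged_clone_id = c(rep("X", 40), rep(NA, 60)),
    lineage = c(rep("B", 4), rep("HSPC", 36), rep("B", 6), rep("HSPC", 54)),
    qc_pass = TRUE)
  ts <- transduction_summary(cells)
  expect_equal(ts$barcoded_fraction, 0.4)
  expect_equal(unname(ts$subset_bias["B"]), (4 / 10) / 0.4)  # == 1
  all_bc <- cells
  all_bc$merged_clone_id <- "X"
  expect_true(all(transduction_summary(all_bc)$subset_bias == 1))
  # empty loading: vector-positive cells with no recoverable tag
  vp <- rep(FALSE, 100)
  vp[c(1:40, 41:50)] <- TRUE    # 50 vector-positive, 10 without a tag
  ts2 <- transduction_summary(cells, vector_positive = vp)
  expect_equal(ts2$empty_loading_rate, 10 / 50)
  expect_warning(ts3 <- transduction_summary(cells, rep(FALSE, 100)),
                 "no vector-positive")
  expect_true(is.na(ts3$empty_loading_rate))
})

test_that("trajectory subsets return member cells of labelled clones", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:20),
                      merged_clone_id = c(rep("L", 12), rep(NA, 8)))
  calls <- data.frame(clone_id = c("L", "M"),
                      bias_label = c("lymphoid", "myeloid"))
  expect_equal(length(subset_for_trajectory(cells, calls,
                                            label = "lymphoid")), 12L)
  expect_warning(out <- subset_for_trajectory(cells, character(0)),
                 "no cells match")
  expect_equal(length(out), 0L)
})
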