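# Clone-level fate statistics over a clone-by-lineage fate table:
# output value (O1/O2), M-value potency, differentiation-bias scores
# (D1/D2), lymphoid/myeloid bias calls, PL-HSPC labelling, and
# transduction summaries.

#' Default downstream lineage labels
#'
#' Nine downstream hematopoietic lineages used as the default lineage set;
#' any experiment can declare its own via configuration. The HSPC
#' compartment is always labelled "HSPC" and is not part of this set.
#'
#' @return character vector of 9 lineage labels.
#' @export
default_lineages <- function() {
  c("B", "T", "NK", "Mono", "Neu", "DC", "Ery", "MK", "Baso")
}

#' Default lymphoid/myeloid partition of the default lineages
#' @return named list with `lymphoid` and `myeloid` label vectors.
#' @export
default_lineage_groups <- function() {
  list(lymphoid = c("B", "T", "NK"),
       myeloid = c("Mono", "Neu", "DC", "Ery", "MK", "Baso"))
}

#' Build the clone-by-lineage fate table
#'
#' Tallies, per clone, the number of cells in the HSPC compartment and in
#' each downstream lineage, plus compartment totals. Only QC-passing cells
#' enter. Compartment totals count every QC-passing cell — barcoded or not —
#' unless `include_unbarcoded = FALSE`, in which case only cells bearing a
#' clone id are counted in the denominators.
#'
#' @param cells data.frame with columns `cell_id`, `merged_clone_id`
#'   (NA for unbarcoded cells), `lineage`, and optionally `qc_pass`
#'   (default TRUE). A lineage of "HSPC" marks the HSPC compartment.
#' @param lineages ordered downstream lineage labels (default
#'   [default_lineages()]); any other label is a hard error.
#' @param include_unbarcoded whether compartment totals include unbarcoded
#'   cells (default TRUE).
#' @return an object of class `clone_fate_table`: list with `lineages`,
#'   `clone_ids`, `hspc_counts` (named integer), `lineage_counts`
#'   (clone x lineage integer matrix), `n_hspc_total`, `lineage_totals`,
#'   `n_downstream_total`.
#' @export
build_fate_table <- function(cells, lineages = default_lineages(),
                             include_unbarcoded = TRUE) {
  required <- c("cell_id", "merged_clone_id", "lineage")
  missing <- setdiff(required, names(cells))
  assert_that(length(missing) == 0L, "cells table missing column(s): %s",
              paste(missing, collapse = ", "))
  if (is.null(cells$qc_pass)) cells$qc_pass <- TRUE
  cells <- cells[cells$qc_pass, , drop = FALSE]
  unknown <- setdiff(unique(cells$lineage), c("HSPC", lineages))
  assert_that(length(unknown) == 0L, "unknown lineage label: %s",
              unknown[1L])
  barcoded <- !is.na(cells$merged_clone_id)
  totals_mask <- if (include_unbarcoded) rep(TRUE, nrow(cells)) else barcoded
  is_hspc <- cells$lineage == "HSPC"

  clone_ids <- sort(unique(cells$merged_clone_id[barcoded]))
  cf <- factor(cells$merged_clone_id, levels = clone_ids)
  lf <- factor(cells$lineage, levels = lineages)
  hspc_counts <- table(cf[is_hspc])
  lineage_counts <- table(cf[!is_hspc], lf[!is_hspc])
  lineage_totals <- table(lf[!is_hspc & totals_mask])

  structure(list(
    lineages = lineages,
    clone_ids = clone_ids,
    hspc_counts = stats::setNames(as.integer(hspc_counts), clone_ids),
    lineage_counts = matrix(as.integer(lineage_counts),
                            nrow = length(clone_ids),
                            ncol = length(lineages),
                            dimnames = list(clone_ids, lineages)),
    n_hspc_total = sum(is_hspc & totals_mask),
    lineage_totals = stats::setNames(as.integer(lineage_totals), lineages),
    n_downstream_total = sum(!is_hspc & totals_mask)
  ), class = "clone_fate_table")
}

#' @export
print.clone_fate_table <- function(x, ...) {
  cat("clone_fate_table:", length(x$clone_ids), "clones,",
      x$n_hspc_total, "HSPC cells,", x$n_downstream_total,
      "downstream cells in", length(x$lineages), "lineages\n")
  invisible(x)
}

.clone_row <- function(clone_id, table) {
  assert_that(clone_id %in% table$clone_ids,
              "clone '%s' not present in fate table", clone_id)
  list(hspc = table$hspc_counts[[clone_id]],
       per_lineage = table$lineage_counts[clone_id, ],
       downstream = sum(table$lineage_counts[clone_id, ]))
}

.require_hspc_clone <- function(clone_id, row) {
  assert_that(row$hspc >= 1L,
              "clone '%s' is not an HSPC clone (no HSPC cells)", clone_id)
}

#' Clone output value
#'
#' O1 is the clone's share of all downstream (non-HSPC) cells; O2 its share
#' of the HSPC compartment. Their ratio O1/O2 is the output value: below 1
#' the clone is over-represented among HSPCs (self-renewing), above 1 it is
#' over-represented downstream (differentiation-prone).
#'
#' @param clone_id clone (or merged clone) id present in `table` with at
#'   least one HSPC cell.
#' @param table a [build_fate_table()] result.
#' @param thresholds classification thresholds, see [classify_output()].
#' @return list with `clone_id`, `O1`, `O2`, `output_value`, `output_class`.
#' @export
output_value <- function(clone_id, table, thresholds = output_thresholds()) {
  row <- .clone_row(clone_id, table)
  .require_hspc_clone(clone_id, row)
  O1 <- row$downstream / table$n_downstream_total
  O2 <- row$hspc / table$n_hspc_total
  value <- O1 / O2
  list(clone_id = clone_id, O1 = O1, O2 = O2, output_value = value,
       output_class = classify_output(value, thresholds))
}

#' Output classification thresholds
#'
#' All inequalities are strict; values falling in the gaps
#' \[`low_max`, `med_low`\] and \[`med_high`, `high_min`\] (boundaries
#' included) are left `unclassified`.
#'
#' @param low_max low class upper bound (default 0.4).
#' @param med_low,med_high medium class open interval (default 0.8, 1.2).
#' @param high_min high class lower bound (default 2.0).
#' @return named list of thresholds.
#' @export
output_thresholds <- function(low_max = 0.4, med_low = 0.8,
                              med_high = 1.2, high_min = 2.0) {
  assert_that(low_max <= med_low && med_low < med_high &&
                med_high <= high_min,
              "output thresholds must be ordered low_max <= med_low < med_high <= high_min")
  list(low_max = low_max, med_low = med_low,
       med_high = med_high, high_min = high_min)
}

#' Classify an output value
#'
#' `low` when value < `low_max`; `med` when `med_low` < value < `med_high`;
#' `high` when value > `high_min`; otherwise `unclassified` (gap values and
#' exact boundaries).
#'
#' @param value numeric vector of non-negative output values.
#' @param thresholds from [output_thresholds()].
#' @return character vector of classes.
#' @export
classify_output <- function(value, thresholds = output_thresholds()) {
  assert_that(all(value >= 0 | is.na(value)),
              "output value must be non-negative")
  out <- rep("unclassified", length(value))
  ok <- !is.na(value)
  out[ok & value < thresholds$low_max] <- "low"
  out[ok & value > thresholds$med_low & value < thresholds$med_high] <- "med"
  out[ok & value > thresholds$high_min] <- "high"
  out[!ok] <- NA_character_
  out
}

#' Clone M-value and potency class
#'
#' The M-value counts the distinct downstream lineages in which the clone's
#' barcode is observed (at least one cell). With L downstream lineages:
#' M = 0 is `none`, M = 1 `unipotent`, 2..L-1 `multipotent`, and M = L
#' `pluripotent`.
#'
#' @inheritParams output_value
#' @return list with `clone_id`, `m_value`, `potency_class`.
#' @export
m_value <- function(clone_id, table) {
  row <- .clone_row(clone_id, table)
  .require_hspc_clone(clone_id, row)
  m <- sum(row$per_lineage >= 1L)
  list(clone_id = clone_id, m_value = m,
       potency_class = potency_class(m, length(table$lineages)))
}

#' @rdname m_value
#' @param m integer M-value(s).
#' @param n_lineages number of downstream lineages.
#' @export
potency_class <- function(m, n_lineages) {
  assert_that(all(m >= 0L & m <= n_lineages),
              "m_value must lie in 0..%d", n_lineages)
  out <- rep("multipotent", length(m))
  out[m == 0L] <- "none"
  out[m == 1L] <- "unipotent"
  out[m == n_lineages] <- "pluripotent"
  out
}

#' Differentiation-bias score for one clone and lineage
#'
#' D1 is the clone's share within the lineage; D2 its share of the whole
#' downstream compartment. Their ratio D1/D2 exceeds 1 when the clone is
#' over-represented in that lineage. With `universe = "all"` the HSPC
#' compartment is included in both D2's numerator and denominator (an
#' alternative reading of "all lineages"; the downstream reading is the
#' default and the one used throughout the pipeline).
#'
#' @inheritParams output_value
#' @param lineage downstream lineage label.
#' @param universe denominator universe for D2: "downstream" (default) or
#'   "all".
#' @return list with `clone_id`, `lineage`, `D1`, `D2`, `score`.
#' @export
bias_score <- function(clone_id, lineage, table,
                       universe = c("downstream", "all")) {
  universe <- match.arg(universe)
  assert_that(lineage %in% table$lineages,
              "lineage '%s' not in fate table", lineage)
  row <- .clone_row(clone_id, table)
  D1 <- row$per_lineage[[lineage]] / table$lineage_totals[[lineage]]
  if (universe == "downstream") {
    D2 <- row$downstream / table$n_downstream_total
  } else {
    D2 <- (row$downstream + row$hspc) /
      (table$n_downstream_total + table$n_hspc_total)
  }
  assert_that(D2 > 0, "clone '%s' absent downstream (D2 == 0)", clone_id)
  list(clone_id = clone_id, lineage = lineage, D1 = D1, D2 = D2,
       score = D1 / D2)
}

#' Bias scores for all clones and lineages
#'
#' @inheritParams output_value
#' @return numeric matrix clone x lineage of D1/D2 scores; rows for clones
#'   absent downstream (D2 = 0) are NA.
#' @export
bias_matrix <- function(table) {
  m <- matrix(NA_real_, nrow = length(table$clone_ids),
              ncol = length(table$lineages),
              dimnames = list(table$clone_ids, table$lineages))
  down <- rowSums(table$lineage_counts)
  d2 <- down / table$n_downstream_total
  has <- d2 > 0
  if (any(has)) {
    d1 <- sweep(table$lineage_counts[has, , drop = FALSE], 2L,
                table$lineage_totals, "/")
    m[has, ] <- d1 / d2[has]
  }
  m
}

#' Call lymphoid/myeloid differentiation bias per clone
#'
#' Downstream lineages are partitioned into a lymphoid and a myeloid group.
#' For each group the bias score is computed on group aggregates: D1 =
#' clone's cells in the group / group total, D2 = clone's downstream cells /
#' downstream total. A clone is labelled with a group when that group's
#' score exceeds `threshold` while the opposite group's score is below 1;
#' clones with fewer than `min_clone_cells` downstream cells are labelled
#' `none`.
#'
#' @inheritParams output_value
#' @param groups named list with `lymphoid` and `myeloid` character vectors
#'   partitioning `table$lineages`; an unassigned lineage is a hard error.
#' @param threshold group score required to call a bias (default 2.0).
#' @param min_clone_cells minimum downstream cells per clone (default 10).
#' @return data.frame `clone_id`, `n_downstream`, `lymphoid_score`,
#'   `myeloid_score`, `bias_label` in {lymphoid, myeloid, none}.
#' @export
call_bias <- function(table, groups = default_lineage_groups(),
                      threshold = 2.0, min_clone_cells = 10L) {
  assigned <- c(groups$lymphoid, groups$myeloid)
  unassigned <- setdiff(table$lineages, assigned)
  assert_that(length(unassigned) == 0L,
              "lineage '%s' not assigned to a lymphoid/myeloid group",
              unassigned[1L])
  assert_that(!anyDuplicated(assigned) &&
                all(assigned %in% table$lineages),
              "lineage groups must partition the table's lineages")
  group_score <- function(group_lineages) {
    gl <- intersect(table$lineages, group_lineages)
    g_total <- sum(table$lineage_totals[gl])
    g_count <- rowSums(table$lineage_counts[, gl, drop = FALSE])
    d1 <- g_count / g_total
    d2 <- rowSums(table$lineage_counts) / table$n_downstream_total
    ifelse(d2 > 0, d1 / d2, NA_real_)
  }
  lym <- group_score(groups$lymphoid)
  mye <- group_score(groups$myeloid)
  n_down <- rowSums(table$lineage_counts)
  label <- rep("none", length(table$clone_ids))
  label[!is.na(lym) & lym > threshold & !is.na(mye) & mye < 1] <- "lymphoid"
  label[!is.na(mye) & mye > threshold & !is.na(lym) & lym < 1] <- "myeloid"
  label[n_down < min_clone_cells] <- "none"
  data.frame(clone_id = table$clone_ids, n_downstream = as.integer(n_down),
             lymphoid_score = lym, myeloid_score = mye, bias_label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label PL-HSPC clones
#'
#' PL-HSPCs are the high-stemness subset: clones that are pluripotent
#' (barcode observed in every downstream lineage) and at the same time
#' low- or medium-output.
#'
#' @param output_results data.frame with `clone_id` and `output_class`.
#' @param potency_results data.frame with `clone_id` and `potency_class`.
#'   Both must cover the same clones.
#' @return character vector of PL-HSPC clone ids.
#' @export
label_pl_hspcs <- function(output_results, potency_results) {
  assert_that(setequal(output_results$clone_id, potency_results$clone_id),
              "output and potency results must cover the same clones")
  m <- merge(output_results[, c("clone_id", "output_class")],
             potency_results[, c("clone_id", "potency_class")],
             by = "clone_id")
  sort(m$clone_id[m$potency_class == "pluripotent" &
                    m$output_class %in% c("low", "med")])
}

#' Transduction summary
#'
#' Counts barcode-positive cells overall and per lineage among QC-passing
#' cells. `subset_bias` is each lineage's barcoded fraction relative to the
#' global barcoded fraction (1 when barcode status is independent of
#' lineage). When a per-cell `vector_positive` flag is supplied the empty
#' loading rate — vector-positive cells with no recoverable tag, as a share
#' of vector-positive cells — is reported as well.
#'
#' @param cells data.frame with `merged_clone_id`, `lineage` and optionally
#'   `qc_pass`.
#' @param vector_positive optional logical vector, one entry per row of
#'   `cells`, flagging cells with evidence of vector integration.
#' @return list with `n_cells`, `n_barcoded`, `barcoded_fraction`,
#'   `per_subset_fraction`, `subset_bias`, and `empty_loading_rate`
#'   (NA unless flags are supplied; NA with a warning when no cell is
#'   vector-positive).
#' @export
transduction_summary <- function(cells, vector_positive = NULL) {
  if (!is.null(vector_positive)) {
    assert_that(length(vector_positive) == nrow(cells),
                "vector_positive must have one entry per cell")
  }
  if (is.null(cells$qc_pass)) cells$qc_pass <- TRUE
  keep <- cells$qc_pass
  cells <- cells[keep, , drop = FALSE]
  if (!is.null(vector_positive)) vector_positive <- vector_positive[keep]
  barcoded <- !is.na(cells$merged_clone_id)
  n <- nrow(cells)
  frac <- if (n > 0) mean(barcoded) else NA_real_
  per <- tapply(barcoded, cells$lineage, mean)
  per <- stats::setNames(as.numeric(per), names(per))
  bias <- if (!is.na(frac) && frac > 0) per / frac else per * NA_real_
  empty <- NA_real_
  if (!is.null(vector_positive)) {
    nv <- sum(vector_positive)
    if (nv == 0L) {
      warning("no vector-positive cells; empty loading rate undefined")
    } else {
      empty <- sum(vector_positive & !barcoded) / nv
    }
  }
  list(n_cells = n, n_barcoded = sum(barcoded), barcoded_fraction = frac,
       per_subset_fraction = per, subset_bias = bias,
       empty_loading_rate = empty)
}

#' Select cells belonging to clones with a given bias label
#'
#' Returns every cell — HSPC and downstream — whose clone carries the
#' requested bias label (or belongs to an explicit clone set), for export
#' to external trajectory-inference tools.
#'
#' @param cells data.frame with `cell_id` and `merged_clone_id`.
#' @param clones either a character vector of clone ids, or a data.frame
#'   from [call_bias()] combined with `label`.
#' @param label bias label to select when `clones` is a [call_bias()]
#'   result.
#' @return character vector of cell ids (empty, with a warning, when no
#'   clone matches).
#' @export
subset_for_trajectory <- function(cells, clones, label = NULL) {
  if (is.data.frame(clones)) {
    assert_that(!is.null(label), "label required with a call_bias result")
    clones <- clones$clone_id[clones$bias_label == label]
  }
  ids <- cells$cell_id[!is.na(cells$merged_clone_id) &
                         cells$merged_clone_id %in% clones]
  if (!length(ids)) warning("no cells match the requested clone set")
  ids
}

#' Assemble per-clone fate results
#'
#' Computes, for every clone with at least one HSPC cell, the output value
#' and class, M-value and potency class, and the lineage with the highest
#' bias score. Clones never observed in HSPCs carry no fate statistics and
#' are omitted.
#'
#' @param table a [build_fate_table()] result.
#' @param thresholds from [output_thresholds()].
#' @return data.frame with the columns written by [write_fate_results()].
#' @export
compute_fate_results <- function(table, thresholds = output_thresholds()) {
  hspc_clones <- table$clone_ids[table$hspc_counts >= 1L]
  bias <- bias_matrix(table)
  rows <- lapply(hspc_clones, function(cl) {
    ov <- output_value(cl, table, thresholds)
    mv <- m_value(cl, table)
    b <- bias[cl, ]
    if (all(is.na(b))) {
      top_lin <- NA_character_
      top_score <- NA_real_
    } else {
      top <- which.max(b)
      top_lin <- table$lineages[top]
      top_score <- b[[top]]
    }
    data.frame(clone_tag = cl,
               n_hspc = table$hspc_counts[[cl]],
               n_downstream_total = sum(table$lineage_counts[cl, ]),
               O1 = ov$O1, O2 = ov$O2,
               output_value = ov$output_value,
               output_class = ov$output_class,
               m_value = mv$m_value,
               potency_class = mv$potency_class,
               top_bias_lineage = top_lin,
               top_bias_score = top_score,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(clone_tag = character(0), n_hspc = integer(0),
                      n_downstream_total = integer(0), O1 = numeric(0),
                      O2 = numeric(0), output_value = numeric(0),
                      output_class = character(0), m_value = integer(0),
                      potency_class = character(0),
                      top_bias_lineage = character(0),
                      top_bias_score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
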