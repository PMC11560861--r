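# TSV readers/writers for the tables the pipeline exchanges with external
# tools (clustering/annotation suites upstream, trajectory tools downstream).

#' Read a per-cell lineage annotation table
#'
#' The annotation TSV is the integration point with external clustering and
#' annotation tools. Required columns: `cell_id`, `lineage`, `compartment`
#' ("HSPC" or "downstream"); optional: `qc_pass` (default TRUE), `doublet`
#' (default FALSE).
#'
#' @param path TSV file with a header.
#' @param lineages optional declared set of downstream lineage labels; when
#'   supplied, any label outside `c(lineages, "HSPC")` is rejected.
#' @return data.frame with columns `cell_id`, `lineage`, `compartment`,
#'   `is_hspc`, `qc_pass`, `doublet`.
#' @export
read_cell_annotation <- function(path, lineages = NULL) {
  df <- read_tsv_strict(path)
  required <- c("cell_id", "lineage", "compartment")
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0L,
              "annotation file missing required column(s): %s",
              paste(missing, collapse = ", "))
  dup <- df$cell_id[duplicated(df$cell_id)]
  assert_that(length(dup) == 0L,
              "duplicate cell_id in annotation: %s", dup[1L])
  if (is.null(df$qc_pass)) df$qc_pass <- TRUE
  if (is.null(df$doublet)) df$doublet <- FALSE
  df$qc_pass <- as.logical(df$qc_pass)
  df$doublet <- as.logical(df$doublet)
  bad_comp <- setdiff(unique(df$compartment), c("HSPC", "downstream"))
  assert_that(length(bad_comp) == 0L,
              "unknown compartment label: %s", bad_comp[1L])
  # compartment and lineage must agree: HSPC is its own lineage label
  clash <- (df$lineage == "HSPC") != (df$compartment == "HSPC")
  assert_that(!any(clash),
              "cell %s: lineage/compartment disagree (HSPC lineage implies HSPC compartment)",
              df$cell_id[which(clash)[1L]])
  if (!is.null(lineages)) {
    unknown <- setdiff(unique(df$lineage), c(lineages, "HSPC"))
    assert_that(length(unknown) == 0L,
                "unknown lineage label: %s", unknown[1L])
  }
  df$is_hspc <- df$compartment == "HSPC"
  df[, c("cell_id", "lineage", "compartment", "is_hspc", "qc_pass", "doublet")]
}

#' @rdname read_cell_annotation
#' @param annotation data.frame as returned by [read_cell_annotation()].
#' @export
write_cell_annotation <- function(annotation, path) {
  cols <- c("cell_id", "lineage", "compartment", "qc_pass", "doublet")
  write_tsv_strict(annotation[, intersect(cols, names(annotation))], path)
}

FATE_RESULT_COLUMNS <- c("clone_tag", "n_hspc", "n_downstream_total",
                         "O1", "O2", "output_value", "output_class",
                         "m_value", "potency_class",
                         "top_bias_lineage", "top_bias_score")

#' Write per-clone fate results
#'
#' One row per HSPC clone with its compartment counts, output value and
#' class, M-value and potency class, and strongest lineage bias. Floats are
#' written at fixed 6-decimal precision so output is byte-stable across
#' runs.
#'
#' @param results data.frame as produced by [compute_fate_results()].
#' @param path output TSV path.
#' @export
write_fate_results <- function(results, path) {
  missing <- setdiff(FATE_RESULT_COLUMNS, names(results))
  assert_that(length(missing) == 0L,
              "fate results missing column(s): %s",
              paste(missing, collapse = ", "))
  out <- results[, FATE_RESULT_COLUMNS, drop = FALSE]
  for (col in c("O1", "O2", "output_value", "top_bias_score")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA, sprintf("%.6f", out[[col]]))
  }
  write_tsv_strict(out, path)
}

#' @rdname write_fate_results
#' @export
read_fate_results <- function(path) {
  df <- read_tsv_strict(path)
  for (col in c("O1", "O2", "output_value", "top_bias_score")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read a per-cell QC metrics table
#'
#' Required columns: `cell_id`, `n_genes`, `n_umis`, `mito_fraction`;
#' optional `doublet` (default FALSE).
#'
#' @param path TSV file.
#' @return data.frame of QC metrics.
#' @export
read_qc_metrics <- function(path) {
  df <- read_tsv_strict(path)
  required <- c("cell_id", "n_genes", "n_umis", "mito_fraction")
  missing <- setdiff(required, names(df))
  assert_that(length(missing) == 0L,
              "QC metrics missing required column(s): %s",
              paste(missing, collapse = ", "))
  if (is.null(df$doublet)) df$doublet <- FALSE
  df$doublet <- as.logical(df$doublet)
  assert_that(all(df$mito_fraction >= 0 & df$mito_fraction <= 1),
              "mito_fraction must lie in [0, 1]")
  assert_that(all(df$n_genes >= 0) && all(df$n_umis >= 0),
              "n_genes and n_umis must be non-negative")
  df
}
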