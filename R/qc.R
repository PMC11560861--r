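# Per-cell quality filters producing the analysis cell set.

#' IQR filter on genes detected per cell
#'
#' Removes cells whose detected-gene count falls strictly below Q1 - IQR or
#' strictly above Q3 + IQR of the per-cell distribution. Quartiles are
#' computed with linear interpolation between order statistics
#' (`stats::quantile` type 7); the boundary itself is kept.
#'
#' @param metrics data.frame with an `n_genes` column, or a numeric vector
#'   of gene counts. At least 4 cells are required for quartiles to be
#'   meaningful.
#' @return logical keep mask, one entry per cell.
#' @export
iqr_gene_filter <- function(metrics) {
  x <- if (is.data.frame(metrics)) metrics$n_genes else metrics
  assert_that(!is.null(x) && is.numeric(x), "n_genes column required")
  assert_that(length(x) >= 4L, "too few cells for IQR filter (need >= 4)")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  x >= q[1L] - iqr & x <= q[2L] + iqr
}

#' Mitochondrial-fraction filter
#'
#' Removes cells whose mitochondrial RNA fraction exceeds 10% (strictly
#' greater; exactly 0.10 is kept).
#'
#' @param metrics data.frame with a `mito_fraction` column, or a numeric
#'   vector of fractions in \[0, 1\].
#' @param max_fraction removal threshold (default 0.10).
#' @return logical keep mask.
#' @export
mito_filter <- function(metrics, max_fraction = 0.10) {
  x <- if (is.data.frame(metrics)) metrics$mito_fraction else metrics
  assert_that(!is.null(x) && is.numeric(x), "mito_fraction column required")
  assert_that(all(x >= 0 & x <= 1), "mito_fraction must lie in [0, 1]")
  x <= max_fraction
}

#' Combine the per-cell quality filters
#'
#' A cell passes QC when it passes the gene-count IQR filter, the
#' mitochondrial filter, and is not flagged as a doublet. Doublet flags are
#' consumed from the metrics table (computed by an external tool), never
#' recomputed here.
#'
#' @param metrics data.frame with columns `cell_id`, `n_genes`,
#'   `mito_fraction` and optionally `doublet` (default FALSE).
#' @return the metrics data.frame with added logical columns `iqr_pass`,
#'   `mito_pass` and `qc_pass`.
#' @export
combine_qc <- function(metrics) {
  assert_that(is.data.frame(metrics), "metrics must be a data.frame")
  if (is.null(metrics$doublet)) metrics$doublet <- FALSE
  metrics$iqr_pass <- iqr_gene_filter(metrics)
  metrics$mito_pass <- mito_filter(metrics)
  metrics$qc_pass <- metrics$iqr_pass & metrics$mito_pass & !metrics$doublet
  metrics
}
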