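# Run configuration and the capture -> qc -> stats pipeline composition.

RUN_CONFIG_KEYS <- c("seed", "construct", "lineages", "lineage_groups",
                     "thresholds", "denominators", "paths")
THRESHOLD_KEYS <- c("low_max", "med_low", "med_high", "high_min",
                    "bias", "min_clone_cells", "min_umi_support")
DENOMINATOR_KEYS <- c("bias_universe", "include_unbarcoded")
PATH_KEYS <- c("r1", "r2", "resolved", "annotation", "qc_metrics", "outdir")

#' Build and validate a run configuration
#'
#' A run configuration carries every tunable of the pipeline: the construct
#' spec, classification and bias thresholds, the lineage set and its
#' lymphoid/myeloid grouping, denominator toggles, input/output paths and
#' the seed. Unknown keys anywhere in the structure are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param config a named list (e.g. parsed from JSON) with any of the keys
#'   `seed`, `construct`, `lineages`, `lineage_groups`, `thresholds`,
#'   `denominators`, `paths`.
#' @return a validated, fully defaulted list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  assert_that(length(unknown) == 0L, "unknown run config key: %s",
              unknown[1L])
  for (part in list(c("thresholds", list(THRESHOLD_KEYS)),
                    c("denominators", list(DENOMINATOR_KEYS)),
                    c("paths", list(PATH_KEYS)))) {
    bad <- setdiff(names(config[[part[[1L]]]]), part[[2L]])
    assert_that(length(bad) == 0L, "unknown %s key: %s", part[[1L]], bad[1L])
  }
  thresholds <- utils::modifyList(
    list(low_max = 0.4, med_low = 0.8, med_high = 1.2, high_min = 2.0,
         bias = 2.0, min_clone_cells = 10L, min_umi_support = 1L),
    as.list(config$thresholds))
  denominators <- utils::modifyList(
    list(bias_universe = "downstream", include_unbarcoded = TRUE),
    as.list(config$denominators))
  assert_that(denominators$bias_universe %in% c("downstream", "all"),
              "bias_universe must be 'downstream' or 'all'")
  construct <- if (is.null(config$construct)) {
    default_construct()
  } else if (inherits(config$construct, "construct_spec")) {
    config$construct
  } else {
    do.call(construct_spec, config$construct[
      intersect(names(config$construct), names(formals(construct_spec)))])
  }
  construct$min_umi_support <- as.integer(thresholds$min_umi_support)
  lineages <- if (is.null(config$lineages)) default_lineages() else
    as.character(config$lineages)
  groups <- if (is.null(config$lineage_groups)) {
    if (identical(lineages, default_lineages())) default_lineage_groups()
    else NULL
  } else {
    lapply(config$lineage_groups, as.character)
  }
  structure(list(seed = if (is.null(config$seed)) 1L else
    as.integer(config$seed),
    construct = construct, lineages = lineages,
    lineage_groups = groups, thresholds = thresholds,
    denominators = denominators,
    paths = as.list(config$paths)), class = "run_config")
}

#' @rdname run_config
#' @param path JSON file holding the configuration.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), "run config not found: %s", path)
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.log_line <- function(con, stage, ...) {
  rec <- c(list(stage = stage,
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, force = TRUE,
                              digits = NA), con)
}

#' Run the full capture -> QC -> fate-statistics pipeline
#'
#' Stages: (1) barcode capture from paired FASTQ (skipped when a resolved
#' cell-to-clone table is supplied instead); (2) per-cell QC (from a
#' metrics table when given, otherwise the annotation's `qc_pass` flags);
#' (3) fate table construction and clone statistics. Artifacts written to
#' `outdir`: `resolved.tsv`, `fate.tsv`, `bias.tsv`, `summary.json` and a
#' line-delimited JSON `run_log.jsonl` recording the config hash, package
#' version, per-stage statistics and every toggle in effect. Any stage
#' failure aborts with an error naming the stage.
#'
#' @param config a [run_config()] (or plain list accepted by it). Paths
#'   used: `r1`/`r2` (FASTQ) or `resolved` (TSV from a previous capture),
#'   `annotation` (required), `qc_metrics` (optional), `outdir` (required).
#' @return invisibly, a list with the resolved cells table, the fate table,
#'   fate results, bias calls and the transduction summary.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  paths <- config$paths
  assert_that(!is.null(paths$outdir), "paths$outdir is required")
  assert_that(!is.null(paths$annotation), "paths$annotation is required")
  dir.create(paths$outdir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(paths$outdir, "run_log.jsonl"), "w")
  on.exit(close(log_con))
  .log_line(log_con, "start",
            config_hash = .config_hash(unclass(config)),
            package_version = as.character(utils::packageVersion("clonefate")),
            seed = config$seed,
            thresholds = config$thresholds,
            denominators = config$denominators)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  annotation <- stage("annotation", {
    assert_that(file.exists(paths$annotation),
                "annotation file not found: %s", paths$annotation)
    read_cell_annotation(paths$annotation, lineages = config$lineages)
  })

  resolved <- stage("capture", {
    if (!is.null(paths$r1) || !is.null(paths$r2)) {
      assert_that(!is.null(paths$r1) && !is.null(paths$r2),
                  "both r1 and r2 FASTQ paths are required for capture")
      pairs <- read_fastq_pairs(paths$r1, paths$r2)
      cap <- capture_reads(pairs, config$construct)
      .log_line(log_con, "capture", stats = cap$stats)
      collapsed <- correct_umis(cap$calls)
      assigned <- assign_cells(collapsed, config$construct)
      resolve_multibarcode(assigned)
    } else {
      assert_that(!is.null(paths$resolved),
                  "either r1/r2 FASTQ or a resolved table is required")
      assert_that(file.exists(paths$resolved),
                  "resolved table not found: %s", paths$resolved)
      read_tsv_strict(paths$resolved)
    }
  })
  write_tsv_strict(resolved, file.path(paths$outdir, "resolved.tsv"))

  qc <- stage("qc", {
    if (!is.null(paths$qc_metrics)) {
      metrics <- read_qc_metrics(paths$qc_metrics)
      metrics <- combine_qc(metrics)
      .log_line(log_con, "qc", quartile_method = "type 7 (linear interpolation)",
                n_cells = nrow(metrics), n_pass = sum(metrics$qc_pass))
      stats::setNames(metrics$qc_pass, metrics$cell_id)
    } else {
      stats::setNames(annotation$qc_pass & !annotation$doublet,
                      annotation$cell_id)
    }
  })

  res <- stage("stats", {
    cells <- annotation
    idx <- match(cells$cell_id, resolved$cell_id)
    cells$merged_clone_id <- resolved$merged_clone_id[idx]
    cells$qc_pass <- !is.na(qc[cells$cell_id]) & qc[cells$cell_id]
    tab <- build_fate_table(
      cells, lineages = config$lineages,
      include_unbarcoded = config$denominators$include_unbarcoded)
    thresholds <- do.call(output_thresholds,
                          config$thresholds[c("low_max", "med_low",
                                              "med_high", "high_min")])
    results <- compute_fate_results(tab, thresholds)
    bias <- bias_matrix(tab)
    bias_calls <- if (!is.null(config$lineage_groups)) {
      call_bias(tab, config$lineage_groups,
                threshold = config$thresholds$bias,
                min_clone_cells = config$thresholds$min_clone_cells)
    }
    summary <- transduction_summary(cells)
    pl <- label_pl_hspcs(results[, c("clone_tag", "output_class")] |>
                           stats::setNames(c("clone_id", "output_class")),
                         results[, c("clone_tag", "potency_class")] |>
                           stats::setNames(c("clone_id", "potency_class")))
    .log_line(log_con, "stats", n_clones = length(tab$clone_ids),
              n_hspc_clones = nrow(results),
              n_pl_hspc = length(pl),
              bias_universe = config$denominators$bias_universe,
              include_unbarcoded = config$denominators$include_unbarcoded)
    list(cells = cells, table = tab, results = results, bias = bias,
         bias_calls = bias_calls, summary = summary, pl_hspcs = pl)
  })

  stage("write", {
    write_fate_results(res$results, file.path(paths$outdir, "fate.tsv"))
    bias_long <- data.frame(
      clone_id = rep(rownames(res$bias), ncol(res$bias)),
      lineage = rep(colnames(res$bias), each = nrow(res$bias)),
      score = as.vector(res$bias), stringsAsFactors = FALSE)
    write_tsv_strict(bias_long, file.path(paths$outdir, "bias.tsv"))
    if (!is.null(res$bias_calls)) {
      write_tsv_strict(res$bias_calls,
                       file.path(paths$outdir, "bias_calls.tsv"))
    }
    jsonlite::write_json(
      c(res$summary[c("n_cells", "n_barcoded", "barcoded_fraction")],
        list(per_subset_fraction = as.list(res$summary$per_subset_fraction),
             subset_bias = as.list(res$summary$subset_bias),
             empty_loading_rate = res$summary$empty_loading_rate,
             pl_hspcs = res$pl_hspcs)),
      file.path(paths$outdir, "summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  })
  .log_line(log_con, "done")
  invisible(res)
}
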