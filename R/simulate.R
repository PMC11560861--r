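# Clone population simulator with known ground truth: output regimes,
# potency (seeded lineage count), Dirichlet lineage bias, detection
# dropout, and (optionally) raw reads carrying the barcode cassette.

#' Simulation configuration
#'
#' Parameterizes a ground-truth clone population. Each clone draws an
#' output regime (an expected output value v), an HSPC cell count from
#' `clone_size`, and a downstream cell count with expectation
#' v x n_hspc x `downstream_expansion`, so that the expected output value
#' of the clone equals v exactly (the downstream compartment total is fixed
#' at `downstream_expansion` times the HSPC total, topped up with
#' unbarcoded background cells). Downstream cells are allocated over a
#' seeded lineage subset (size drawn from `potency_weights`) with
#' Dirichlet-distributed weights.
#'
#' @param seed integer RNG seed; the entire simulation is a deterministic
#'   function of the configuration.
#' @param n_clones number of barcoded founder clones.
#' @param lineages downstream lineage labels (default [default_lineages()]).
#' @param clone_size list describing the per-clone HSPC cell count:
#'   `list(dist = "nbinom", mu, size)` (truncated to >= 1) or
#'   `list(dist = "fixed", n)` or `list(dist = "shifted_pois", min, lambda)`
#'   giving `min + rpois(lambda)`.
#' @param output_regimes data.frame with columns `regime`, `value`
#'   (expected output value, > 0) and `share` (mixture weights summing
#'   to 1).
#' @param potency_weights probability weights over the number of seeded
#'   lineages 1..length(lineages) (default uniform).
#' @param bias_concentration Dirichlet concentration for lineage weights
#'   within the seeded set (default 10; larger = less clone-to-clone
#'   variability).
#' @param bias_multipliers optional named per-lineage multipliers applied
#'   to the Dirichlet concentration (e.g. `c(B = 5)` makes clones seeded in
#'   B allocate ~5x weight there).
#' @param unbarcoded_fraction fraction of the HSPC compartment carrying no
#'   barcode (default 0.75, i.e. ~25% of HSPCs barcoded). Must leave
#'   (1 - fraction) x mean regime value <= 1, or the clone downstream
#'   demand exceeds the compartment (infeasible; hard error).
#' @param downstream_expansion downstream compartment total as a multiple
#'   of the HSPC compartment total (default 8).
#' @param detection_dropout probability in \[0, 1) that a barcoded cell's
#'   tag goes unobserved (cell kept, barcode missing).
#' @param error_rates per-base substitution rates used by [emit_reads()]:
#'   named list with `cell_barcode`, `umi`, `anchor`, `tag` (defaults 0).
#' @param construct a [construct_spec()] for read emission.
#' @param umis_per_cell,reads_per_umi Poisson intensities; counts are drawn
#'   as 1 + rpois(lambda) so every barcoded cell yields at least one read.
#' @param read2_length cDNA read length (default 100).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clones = 100L,
                       lineages = default_lineages(),
                       clone_size = list(dist = "nbinom", mu = 5, size = 2),
                       output_regimes = data.frame(
                         regime = c("low", "med", "high"),
                         value = c(0.2, 1.0, 3.0),
                         share = c(1, 1, 1) / 3),
                       potency_weights = NULL,
                       bias_concentration = 10,
                       bias_multipliers = NULL,
                       unbarcoded_fraction = 0.75,
                       downstream_expansion = 8,
                       detection_dropout = 0,
                       error_rates = list(),
                       construct = default_construct(),
                       umis_per_cell = 1,
                       reads_per_umi = 0.5,
                       read2_length = 100L) {
  if (is.null(potency_weights)) {
    potency_weights <- rep(1, length(lineages))
  }
  er <- list(cell_barcode = 0, umi = 0, anchor = 0, tag = 0)
  er[names(error_rates)] <- error_rates
  cfg <- structure(list(
    seed = as.integer(seed), n_clones = as.integer(n_clones),
    lineages = lineages, clone_size = clone_size,
    output_regimes = output_regimes, potency_weights = potency_weights,
    bias_concentration = bias_concentration,
    bias_multipliers = bias_multipliers,
    unbarcoded_fraction = unbarcoded_fraction,
    downstream_expansion = downstream_expansion,
    detection_dropout = detection_dropout,
    error_rates = er, construct = construct,
    umis_per_cell = umis_per_cell, reads_per_umi = reads_per_umi,
    read2_length = as.integer(read2_length)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  r <- config$output_regimes
  assert_that(abs(sum(r$share) - 1) < 1e-8, "regime shares must sum to 1")
  assert_that(all(r$value > 0),
              "output regime expected values must be positive (a regime of 0 cannot seed downstream cells)")
  assert_that(config$unbarcoded_fraction >= 0 &&
                config$unbarcoded_fraction < 1,
              "unbarcoded_fraction must lie in [0, 1)")
  assert_that(config$detection_dropout >= 0 &&
                config$detection_dropout < 1,
              "detection_dropout must lie in [0, 1)")
  for (nm in names(config$error_rates)) {
    e <- config$error_rates[[nm]]
    assert_that(e >= 0 && e < 1, "error rate '%s' must lie in [0, 1)", nm)
  }
  assert_that(length(config$potency_weights) == length(config$lineages),
              "potency_weights must have one weight per lineage count 1..L")
  assert_that(config$downstream_expansion > 0,
              "downstream_expansion must be positive")
  validate_construct(config$construct)
  invisible(config)
}

.draw_clone_sizes <- function(cs, n) {
  switch(cs$dist,
         fixed = rep(as.integer(cs$n), n),
         nbinom = pmax(1L, stats::rnbinom(n, mu = cs$mu, size = cs$size)),
         shifted_pois = as.integer(cs$min) + stats::rpois(n, cs$lambda),
         stop(sprintf("unknown clone_size dist '%s'", cs$dist),
              call. = FALSE))
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a barcoded clone population
#'
#' Draws clones with known output regimes, potency and lineage bias, then
#' realizes a full cell table: barcoded HSPC and downstream cells plus
#' unbarcoded background in both compartments. Every seeded lineage
#' receives at least one downstream cell, so the seeded-lineage count is
#' the clone's true M-value at zero dropout. Detection dropout leaves a
#' cell in place with its barcode unobserved.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_result` with elements
#'   `truth` (list: `clones` data.frame with per-clone parameters and
#'   realized counts, `cells` data.frame with true and observed tags),
#'   `annotation` (per-cell lineage annotation table),
#'   `resolved` (observed cell-to-clone table as produced by barcode
#'   capture), and `config`.
#' @export
simulate_clones <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- length(config$lineages)
  r <- config$output_regimes
  regime_idx <- sample.int(nrow(r), config$n_clones, replace = TRUE,
                           prob = r$share)
  v <- r$value[regime_idx]
  n_hspc <- .draw_clone_sizes(config$clone_size, config$n_clones)
  m_seeded <- sample.int(L, config$n_clones, replace = TRUE,
                         prob = config$potency_weights)

  H_barcoded <- sum(n_hspc)
  H_total <- as.integer(ceiling(H_barcoded / (1 - config$unbarcoded_fraction)))
  S <- sum(v * n_hspc)
  assert_that(S <= H_total,
              paste0("infeasible configuration: clone downstream demand ",
                     "(sum of value x HSPC cells = %.1f) exceeds the HSPC ",
                     "total %d; raise unbarcoded_fraction or lower regime ",
                     "values"), S, H_total)
  f <- config$downstream_expansion
  D_total <- as.integer(round(f * H_total))
  c_down <- stats::rpois(config$n_clones, v * n_hspc * f)
  c_down <- pmax(c_down, m_seeded)  # every seeded lineage gets >= 1 cell
  D_bg <- D_total - sum(c_down)
  assert_that(D_bg >= 0,
              "infeasible configuration: realized clone downstream cells exceed the downstream compartment")

  clone_tag <- rand_dna_unique(config$n_clones, config$construct$tag_length)
  mult <- rep(1, L)
  names(mult) <- config$lineages
  if (!is.null(config$bias_multipliers)) {
    mult[names(config$bias_multipliers)] <- config$bias_multipliers
  }

  seeded <- vector("list", config$n_clones)
  weights <- vector("list", config$n_clones)
  counts <- matrix(0L, nrow = config$n_clones, ncol = L,
                   dimnames = list(clone_tag, config$lineages))
  for (i in seq_len(config$n_clones)) {
    sl <- sort(sample(config$lineages, m_seeded[i]))
    seeded[[i]] <- sl
    w <- .rdirichlet(config$bias_concentration * mult[sl])
    weights[[i]] <- stats::setNames(w, sl)
    extra <- c_down[i] - m_seeded[i]
    alloc <- rep(1L, m_seeded[i])
    if (extra > 0L) {
      alloc <- alloc + as.integer(stats::rmultinom(1L, extra, prob = w))
    }
    counts[i, sl] <- alloc
  }

  # background lineage allocation: uniform over lineages
  bg_counts <- as.integer(stats::rmultinom(1L, D_bg, prob = rep(1, L)))

  clones <- data.frame(clone_tag = clone_tag,
                       regime = r$regime[regime_idx],
                       expected_output = v,
                       n_hspc = n_hspc,
                       n_downstream = c_down,
                       m_seeded = m_seeded,
                       seeded_lineages = vapply(seeded, paste, "",
                                                collapse = ","),
                       stringsAsFactors = FALSE)
  clones <- cbind(clones, as.data.frame(counts, stringsAsFactors = FALSE))
  rownames(clones) <- NULL

  # downstream block is clone-major: for each clone, its L lineage counts
  cell_tag <- c(rep(clone_tag, n_hspc),
                rep(NA_character_, H_total - H_barcoded),
                rep(rep(clone_tag, each = L), as.integer(t(counts))),
                rep(NA_character_, D_bg))
  cell_lineage <- c(rep("HSPC", H_total),
                    rep(rep(config$lineages, config$n_clones),
                        as.integer(t(counts))),
                    rep(config$lineages, bg_counts))
  n_cells <- length(cell_tag)
  cell_id <- rand_dna_unique(n_cells, 20L)
  observed <- cell_tag
  if (config$detection_dropout > 0) {
    barcoded <- which(!is.na(cell_tag))
    drop <- barcoded[stats::runif(length(barcoded)) <
                       config$detection_dropout]
    observed[drop] <- NA_character_
  }
  cells <- data.frame(cell_id = cell_id, clone_tag = cell_tag,
                      observed_tag = observed, lineage = cell_lineage,
                      compartment = ifelse(cell_lineage == "HSPC",
                                           "HSPC", "downstream"),
                      stringsAsFactors = FALSE)
  annotation <- data.frame(cell_id = cell_id, lineage = cell_lineage,
                           compartment = cells$compartment,
                           is_hspc = cells$compartment == "HSPC",
                           qc_pass = TRUE, doublet = FALSE,
                           stringsAsFactors = FALSE)
  obs <- which(!is.na(observed))
  resolved <- data.frame(cell_id = cell_id[obs],
                         n_tags = rep(1L, length(obs)),
                         clone_tags = observed[obs],
                         merged_clone_id = observed[obs],
                         umi_support = rep(NA_character_, length(obs)),
                         resolution = rep("single", length(obs)),
                         stringsAsFactors = FALSE)
  structure(list(truth = list(clones = clones, cells = cells),
                 annotation = annotation, resolved = resolved,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", nrow(x$truth$clones), "clones,",
      nrow(x$truth$cells), "cells (",
      sum(!is.na(x$truth$cells$clone_tag)), "barcoded )\n")
  invisible(x)
}

#' Emit FASTQ reads for a simulated population
#'
#' Writes a Read1/Read2 pair for every sequenced molecule of every cell
#' with an observed barcode. Read1 is the 20-base cell barcode followed by
#' a 10-base UMI; Read2 carries random stuffer, the upstream anchor, the
#' clone tag and the downstream anchor at a random feasible offset, padded
#' with stuffer to `read2_length`. Substitution errors are applied per
#' region at the configured rates and book-kept in the manifest.
#'
#' @param sim a [simulate_clones()] result.
#' @param path_r1,path_r2 output FASTQ paths (".gz" for gzip).
#' @param seed RNG seed for read generation (default: simulation seed + 1).
#' @return invisibly, the manifest data.frame: `read_id`, `cell_id`, `umi`,
#'   `clone_tag` (true tag), `cassette_offset`, and per-region error counts
#'   `cell_errors`, `umi_errors`, `up_errors`, `tag_errors`, `down_errors`.
#' @export
emit_reads <- function(sim, path_r1, path_r2,
                       seed = sim$config$seed + 1L) {
  config <- sim$config
  spec <- config$construct
  cassette_len <- nchar(spec$upstream_anchor) + spec$tag_length +
    nchar(spec$downstream_anchor)
  assert_that(cassette_len <= config$read2_length,
              "anchors + tag (%d bases) exceed Read2 length %d",
              cassette_len, config$read2_length)
  set.seed(seed)
  cells <- sim$truth$cells
  cells <- cells[!is.na(cells$observed_tag), , drop = FALSE]
  n_umi <- 1L + stats::rpois(nrow(cells), config$umis_per_cell)
  cell_rep <- rep(seq_len(nrow(cells)), n_umi)
  umi <- rand_dna(length(cell_rep), 10L)
  n_reads <- 1L + stats::rpois(length(cell_rep), config$reads_per_umi)
  mol_rep <- rep(seq_along(cell_rep), n_reads)

  n_total <- length(mol_rep)
  cell_bc <- cells$cell_id[cell_rep][mol_rep]
  read_umi <- umi[mol_rep]
  tag <- cells$observed_tag[cell_rep][mol_rep]

  er <- config$error_rates
  mb <- mutate_bases(cell_bc, er$cell_barcode)
  mu <- mutate_bases(read_umi, er$umi)
  mt <- mutate_bases(tag, er$tag)
  up <- mutate_bases(rep(spec$upstream_anchor, n_total), er$anchor)
  dn <- mutate_bases(rep(spec$downstream_anchor, n_total), er$anchor)

  max_off <- config$read2_length - cassette_len
  offset <- sample.int(max_off + 1L, n_total, replace = TRUE) - 1L
  left <- rand_dna(n_total, max(max_off, 1L))
  left <- substr(left, 1L, pmax(offset, 0L))
  right_len <- max_off - offset
  right <- rand_dna(n_total, max(max_off, 1L))
  right <- substr(right, 1L, right_len)

  read1 <- paste0(mb$seq, mu$seq)
  read2 <- paste0(left, up$seq, mt$seq, dn$seq, right)
  read_id <- sprintf("sim%07d", seq_len(n_total))
  q1 <- strrep("F", 30L)
  q2 <- strrep("F", config$read2_length)
  write_fastq(read_id, read1, rep(q1, n_total), path_r1)
  write_fastq(read_id, read2, rep(q2, n_total), path_r2)
  manifest <- data.frame(read_id = read_id, cell_id = cells$cell_id[cell_rep][mol_rep],
                         umi = read_umi, clone_tag = tag,
                         cassette_offset = offset,
                         cell_errors = mb$n_errors, umi_errors = mu$n_errors,
                         up_errors = up$n_errors, tag_errors = mt$n_errors,
                         down_errors = dn$n_errors,
                         stringsAsFactors = FALSE)
  invisible(manifest)
}

#' Score pipeline estimates against simulation truth
#'
#' @param results per-clone fate results ([compute_fate_results()]).
#' @param truth the `truth` element of a [simulate_clones()] result (or
#'   the result itself).
#' @param bias_calls optional [call_bias()] result to score bias labels
#'   against clones simulated with a dominant lineage multiplier.
#' @return list with `n_clones_scored`, `confusion` (regime x output class
#'   table), `class_match_rate` (per regime), `output_bias` and
#'   `output_rmse` (estimated vs expected output value), and
#'   `potency_exact_rate` (estimated M == seeded lineage count).
#' @export
evaluate_recovery <- function(results, truth, bias_calls = NULL) {
  if (inherits(truth, "sim_result")) truth <- truth$truth
  clones <- truth$clones
  unknown <- setdiff(results$clone_tag, clones$clone_tag)
  assert_that(length(unknown) == 0L,
              "clone id '%s' absent from simulation truth", unknown[1L])
  m <- merge(clones, results, by = "clone_tag")
  regime_levels <- unique(clones$regime)
  expected_class <- classify_output(m$expected_output)
  confusion <- table(factor(m$regime, levels = regime_levels),
                     factor(m$output_class,
                            levels = c("low", "med", "high",
                                       "unclassified")))
  match_rate <- vapply(regime_levels, function(rg) {
    sel <- m$regime == rg
    if (!any(sel)) return(NA_real_)
    mean(m$output_class[sel] == expected_class[sel])
  }, 0)
  err <- m$output_value - m$expected_output
  list(n_clones_scored = nrow(m),
       confusion = confusion,
       class_match_rate = stats::setNames(match_rate, regime_levels),
       output_bias = mean(err),
       output_rmse = sqrt(mean(err^2)),
       potency_exact_rate = mean(m$m_value == m$m_seeded),
       bias_label_rate = if (is.null(bias_calls)) NA_real_ else {
         bm <- merge(clones, bias_calls, by.x = "clone_tag",
                     by.y = "clone_id")
         mean(bm$bias_label != "none")
       })
}
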