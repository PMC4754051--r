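with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

write_stage_csv <- function(df, out_dir, name) {
  if (!is.null(out_dir)) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
}

#' Run the single-cell qPCR analysis pipeline
#'
#' Orchestrates the full Ct-matrix analysis in order: detection calling,
#' housekeeper well QC, cross-chip batch adjustment (skipped for a single
#' chip), re-detection on adjusted values, phenotype and cortical-layer
#' classification, composition tabulation (with a between-group
#' homogeneity test when `group` is given), the permutation co-expression
#' test over all layer-marker pairs among neurons, and PCA with the
#' centroid-distance cluster-separation test between deep- and
#' upper-identity neurons. When `out_dir` is given every stage writes a
#' CSV plus a JSON run manifest.
#'
#' @param ct A [ct_matrix()].
#' @param out_dir Optional output directory (created if needed).
#' @param lod Limit of detection in cycles.
#' @param reference_batch Anchor chip for batch adjustment.
#' @param panel A [marker_panel()].
#' @param n_perm Permutations for the co-expression test.
#' @param seed Seed for all stochastic stages.
#' @param group Optional named vector (by well id) of group labels for the
#'   composition comparison.
#' @return List with `qc`, `adjustment`, `calls`, `composition`,
#'   `composition_test`, `coexpr`, `pca`, `cluster_test` and `summary`
#'   (named list of counts and one-decimal percentages).
#' @export
#' @examples
#' fx <- worked_example_fixture()
#' run_qpcr_pipeline(fx$ct)$summary$pct_neurons
run_qpcr_pipeline <- function(ct, out_dir = NULL, lod = 30,
                              reference_batch = NULL,
                              panel = marker_panel(), n_perm = 10000,
                              seed = 1, group = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  det0 <- with_stage("call_detection", call_detection(ct, lod))
  qc <- with_stage("well_qc", well_qc(det0))
  write_stage_csv(qc$report, out_dir, "well_qc.csv")

  multi_batch <- length(unique(unname(ct$batch))) > 1
  if (multi_batch) {
    ba <- with_stage("batch_adjust",
                     batch_adjust(ct, reference_batch, lod = lod))
    ct_adj <- ba$ct
    adjustment <- ba$adjustment
  } else {
    ct_adj <- ct
    adjustment <- data.frame(batch = unique(unname(ct$batch)), shift = 0)
  }
  write_stage_csv(adjustment, out_dir, "batch_adjustment.csv")

  det <- call_detection(ct_adj, lod)
  calls <- with_stage("classify_cells",
                      classify_cells(det, panel,
                                     wells = qc$valid_wells))
  write_stage_csv(calls, out_dir, "cell_calls.csv")

  comp <- with_stage("composition_table",
                     composition_table(calls, group = if (is.null(group))
                       NULL else unname(group[calls$well_id])))
  comp_test <- NULL
  if (!is.null(group) && nrow(comp) >= 2) {
    comp_test <- with_stage("compare_compositions",
                            compare_compositions(comp, seed = seed))
  }
  if (!is.null(out_dir)) {
    utils::write.csv(as.data.frame(comp),
                     file.path(out_dir, "composition.csv"))
  }

  neurons <- calls$well_id[calls$is_neuron]
  expr <- to_expression(ct_adj, lod)[neurons, , drop = FALSE]
  layer_genes <- c(panel$deep, panel$upper)
  pairs <- t(utils::combn(layer_genes, 2))
  coexpr <- with_stage("perm_corr_test",
                       perm_corr_test(expr, pairs, n_perm = n_perm,
                                      seed = seed))
  write_stage_csv(coexpr, out_dir, "coexpression.csv")

  pca <- with_stage("pca", pca_expr(expr, n_components = 2))
  sep_labels <- calls$layer[calls$is_neuron]
  cluster_test <- NULL
  du <- sep_labels %in% c("deep", "upper")
  if (sum(sep_labels[du] == "deep") >= 3 &&
      sum(sep_labels[du] == "upper") >= 3) {
    cluster_test <- with_stage(
      "cluster_separation_test",
      cluster_separation_test(pca$scores[du, , drop = FALSE],
                              sep_labels[du])
    )
  }
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(well_id = rownames(pca$scores),
                                pca$scores),
                     file.path(out_dir, "pca_scores.csv"),
                     row.names = FALSE)
  }

  n_wells <- nrow(ct$ct)
  n_valid <- length(qc$valid_wells)
  n_neurons <- sum(calls$is_neuron)
  layer <- table(factor(calls$layer[calls$is_neuron],
                        levels = c("deep", "upper", "mixed", "none")))
  n_single <- unname(layer["deep"] + layer["upper"])
  n_layer_pos <- unname(n_single + layer["mixed"])
  n_gaba <- sum(calls$is_gaba)
  pct <- function(a, b) {
    if (b > 0) unname(round(100 * a / b, 1)) else NA_real_
  }
  summary <- list(
    n_wells = n_wells,
    n_valid_wells = n_valid,
    pct_valid_wells = pct(n_valid, n_wells),
    n_neurons = n_neurons,
    pct_neurons = pct(n_neurons, n_valid),
    n_single_layer = n_single,
    pct_single_layer = pct(n_single, n_neurons),
    n_mixed_layer = unname(layer["mixed"]),
    pct_mixed_layer = pct(layer["mixed"], n_neurons),
    n_no_layer = unname(layer["none"]),
    pct_no_layer = pct(layer["none"], n_neurons),
    pct_assignable_of_layer_expressing = pct(n_single, n_layer_pos),
    n_gaba = n_gaba,
    pct_gaba = pct(n_gaba, n_neurons)
  )
  if (!is.null(out_dir)) {
    utils::write.csv(data.frame(metric = names(summary),
                                value = unlist(summary)),
                     file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "cortid",
      version = as.character(utils::packageVersion("cortid")),
      config = list(lod = lod, reference_batch = reference_batch,
                    n_perm = n_perm, seed = seed),
      n_wells = n_wells
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(qc = qc, adjustment = adjustment, calls = calls,
       composition = comp, composition_test = comp_test,
       coexpr = coexpr, pca = pca, cluster_test = cluster_test,
       summary = summary)
}

#' Run the single-cell RNA-seq QC pipeline
#'
#' Computes the per-cell QC report (gene-count, mitochondrial and PCA
#' filters), median-of-ratios size factors and FPKM; when `groups` is
#' supplied it additionally runs the rank-sum stand-in significance flags
#' on QC-passing cells and applies the differential-expression
#' post-filter.
#'
#' @param counts Integer genes x cells matrix.
#' @param annotation Gene annotation data frame.
#' @param out_dir Optional output directory.
#' @param mito_threshold,mad_multiplier Passed to [cell_qc()].
#' @param groups Optional named two-level factor (by cell id) for the DE
#'   post-filter demonstration.
#' @param rule A [de_filter_rule()].
#' @return List with `qc`, `size_factors`, `fpkm`, and (with groups)
#'   `de_table` including the `retained` column.
#' @export
run_rnaseq_qc <- function(counts, annotation, out_dir = NULL,
                          mito_threshold = 0.15, mad_multiplier = 5,
                          groups = NULL, rule = de_filter_rule()) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  qc <- with_stage("cell_qc",
                   cell_qc(counts, annotation, mito_threshold,
                           mad_multiplier))
  write_stage_csv(qc, out_dir, "cell_qc.csv")
  keep <- qc$cell_id[qc$pass]
  kept <- counts[, keep, drop = FALSE]
  sf <- with_stage("size_factors", size_factors(kept))
  write_stage_csv(data.frame(cell_id = names(sf), size_factor = sf),
                  out_dir, "size_factors.csv")
  fk <- with_stage("fpkm", fpkm(kept, annotation))

  de_table <- NULL
  if (!is.null(groups)) {
    g <- as.factor(unname(groups[keep]))
    flags <- with_stage("de_flag_ranksum", de_flag_ranksum(kept, g))
    lv <- levels(g)
    a <- kept[, g == lv[1], drop = FALSE]
    b <- kept[, g == lv[2], drop = FALSE]
    fa <- fk[, g == lv[1], drop = FALSE]
    fb <- fk[, g == lv[2], drop = FALSE]
    de_table <- data.frame(
      gene_id = rownames(kept),
      significant = flags$significant,
      detect_frac_a = rowMeans(a >= 1),
      detect_frac_b = rowMeans(b >= 1),
      mean_fpkm_a = rowMeans(fa),
      mean_fpkm_b = rowMeans(fb),
      stringsAsFactors = FALSE
    )
    de_table <- with_stage("de_post_filter", de_post_filter(de_table, rule))
    write_stage_csv(de_table, out_dir, "de_post_filter.csv")
  }
  list(qc = qc, size_factors = sf, fpkm = fk, de_table = de_table)
}

#' Write a simulated or worked-example fixture to disk
#'
#' Writes the Ct matrix as a wide CSV plus a ground-truth sidecar CSV
#' (`well_id`, `archetype`, `batch`, `is_gaba`).
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [qpcr_sim_config()]; ignored when
#'   `worked_example = TRUE`.
#' @param worked_example Write the deterministic worked-example fixture
#'   instead of a simulation.
#' @return Invisibly, the list returned by the generator.
#' @export
simulate_to_dir <- function(out_dir, config = qpcr_sim_config(),
                            worked_example = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- if (worked_example) worked_example_fixture()
         else simulate_qpcr(config)
  write_ct_table(sim$ct, file.path(out_dir, "ct_matrix.csv"))
  utils::write.csv(sim$truth$wells,
                   file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(sim)
}
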