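#' Assign a cortical-layer category from one well's detection calls
#'
#' `deep` when at least one deep-layer marker and no upper-layer marker is
#' detected, `upper` symmetrically, `mixed` when at least one of each, and
#' `none` when no layer marker is detected.
#'
#' @param detected_row Named logical vector of detection calls for one
#'   well (names are gene symbols).
#' @param panel A [marker_panel()].
#' @return One of `"deep"`, `"upper"`, `"mixed"`, `"none"`.
#' @export
#' @examples
#' row <- c(TBR1 = TRUE, SATB2 = TRUE, BCL11B = FALSE,
#'          CUX1 = FALSE, POU3F2 = FALSE)
#' assign_layer(row)
assign_layer <- function(detected_row, panel = marker_panel()) {
  d <- any(detected_row[panel$deep])
  u <- any(detected_row[panel$upper])
  if (d && u) "mixed" else if (d) "deep" else if (u) "upper" else "none"
}

#' Classify QC-passing wells into phenotypes and layer categories
#'
#' A well is a neuron if any pan-neuronal marker (MAP2, NCAM1, TUBB3) is
#' detected; GABAergic if additionally GAD1 is detected (GAD1 without
#' neuronal markers does not make a GABA call); glial if any glial marker
#' is detected. Neurons get a cortical-layer category via
#' [assign_layer()]; non-neurons carry `NA` there. Wells flagged both
#' neuronal and glial (possible in pathological inputs) are retained and
#' treated as neurons for layer assignment.
#'
#' @param det A `detection_matrix`, usually restricted to QC-passing
#'   wells (see `wells`).
#' @param panel A [marker_panel()].
#' @param wells Optional character vector restricting classification to
#'   these wells (e.g. `well_qc()$valid_wells`).
#' @return Data frame of per-well calls: `well_id`, `batch`, `is_neuron`,
#'   `is_gaba`, `is_glia`, `layer`.
#' @export
classify_cells <- function(det, panel = marker_panel(), wells = NULL) {
  stopifnot(inherits(det, "detection_matrix"))
  check_panel_genes(panel[c("neuron", "deep", "upper", "gaba", "glia")],
                    colnames(det$detected))
  m <- det$detected
  batch <- det$batch
  if (!is.null(wells)) {
    missing <- setdiff(wells, rownames(m))
    if (length(missing) > 0) {
      stop("unknown wells: ", paste(missing, collapse = ", "))
    }
    m <- m[wells, , drop = FALSE]
    batch <- batch[wells]
  }
  is_neuron <- rowSums(m[, panel$neuron, drop = FALSE]) > 0
  is_gaba <- is_neuron & m[, panel$gaba]
  is_glia <- rowSums(m[, panel$glia, drop = FALSE]) > 0
  deep <- rowSums(m[, panel$deep, drop = FALSE]) > 0
  upper <- rowSums(m[, panel$upper, drop = FALSE]) > 0
  layer <- rep(NA_character_, nrow(m))
  layer[is_neuron] <- ifelse(deep[is_neuron] & upper[is_neuron], "mixed",
                      ifelse(deep[is_neuron], "deep",
                      ifelse(upper[is_neuron], "upper", "none")))
  data.frame(well_id = rownames(m), batch = unname(batch),
             is_neuron = unname(is_neuron), is_gaba = unname(is_gaba),
             is_glia = unname(is_glia), layer = layer,
             stringsAsFactors = FALSE)
}

LAYER_LEVELS <- c("deep", "upper", "mixed", "none", "non-neuron")

#' Tabulate cellular composition by group
#'
#' Builds a groups x categories contingency table of cell counts, with
#' layer categories for neurons and a `non-neuron` category for the rest.
#'
#' @param calls Data frame from [classify_cells()].
#' @param group Vector of group labels, one per call (e.g. culture age),
#'   or the name of a column of `calls`. Defaults to a single group.
#' @return Integer matrix (groups x categories).
#' @export
composition_table <- function(calls, group = NULL) {
  if (is.null(group)) {
    group <- rep("all", nrow(calls))
  } else if (is.character(group) && length(group) == 1) {
    if (!group %in% names(calls)) stop("grouping column ", group,
                                       " absent from calls")
    group <- calls[[group]]
  }
  if (length(group) != nrow(calls)) {
    stop("one group label per call required")
  }
  if (anyNA(group)) stop("missing group label")
  category <- ifelse(calls$is_neuron, calls$layer, "non-neuron")
  tab <- table(group = group,
               category = factor(category, levels = LAYER_LEVELS))
  unclass(as.matrix(tab))
}

#' Compare cellular compositions between groups
#'
#' Tests homogeneity of category proportions across groups with a
#' chi-square test; when more than 20% of expected counts fall below 5 the
#' chi-square approximation is unreliable and a Monte-Carlo Fisher exact
#' test (Fisher-Freeman-Halton) is used instead.
#'
#' @param tab Contingency table from [composition_table()] (groups x
#'   categories); all-zero columns are dropped.
#' @param b Monte-Carlo replicates for the exact test.
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `test` (`"chi-square"` or `"fisher-mc"`),
#'   `statistic`, `df`, `p.value`.
#' @export
compare_compositions <- function(tab, b = 10000, seed = 1) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least 2 groups and 2 categories")
  }
  if (any(rowSums(tab) == 0)) {
    stop("group with 0 cells: ",
         paste(rownames(tab)[rowSums(tab) == 0], collapse = ", "))
  }
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (mean(chi$expected < 5) > 0.2) {
    set.seed(seed)
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = b)
    list(test = "fisher-mc", statistic = NA_real_, df = NA_real_,
         p.value = ft$p.value)
  } else {
    list(test = "chi-square",
         statistic = unname(chi$statistic),
         df = unname(chi$parameter),
         p.value = chi$p.value)
  }
}
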