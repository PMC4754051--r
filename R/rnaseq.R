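#' Per-cell detected gene counts
#'
#' A gene is detectable in a cell iff at least one fragment was assigned
#' to it (count >= 1).
#'
#' @param counts Integer genes x cells matrix.
#' @return Named integer vector: detected genes per cell.
#' @export
detectable_genes <- function(counts) {
  colSums(counts >= 1)
}

#' Median-of-ratios library size factors
#'
#' Per-gene geometric means are taken across cells over genes with
#' strictly positive counts in every cell; each cell's factor is the
#' median of its counts divided by those geometric means, the median
#' taken on the log scale as in the reference median-of-ratios
#' implementation.
#'
#' @param counts Integer genes x cells matrix.
#' @param pseudocount Add 1 to every count before estimation; use when no
#'   gene is nonzero in all cells.
#' @return Named numeric vector of positive per-cell factors.
#' @export
#' @examples
#' m <- matrix(c(2, 4, 4, 8), 2, dimnames = list(c("a", "b"), c("c1", "c2")))
#' size_factors(m)
size_factors <- function(counts, pseudocount = FALSE) {
  m <- counts + if (pseudocount) 1 else 0
  use <- rowSums(m > 0) == ncol(m)
  if (!any(use)) {
    stop("no gene has nonzero counts in every cell; ",
         "consider size_factors(..., pseudocount = TRUE)")
  }
  log_geo <- rowMeans(log(m[use, , drop = FALSE]))
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  stats::setNames(sf, colnames(counts))
}

#' Per-cell mitochondrial fragment fraction
#'
#' @param counts Integer genes x cells matrix.
#' @param annotation Data frame with `gene_id` and `is_mito` covering all
#'   matrix genes.
#' @return Named numeric vector in \[0, 1\].
#' @export
mito_fraction <- function(counts, annotation) {
  missing <- setdiff(rownames(counts), annotation$gene_id)
  if (length(missing) > 0) {
    stop("annotation missing genes: ", paste(missing, collapse = ", "))
  }
  is_mito <- annotation$is_mito[match(rownames(counts),
                                      annotation$gene_id)]
  tot <- colSums(counts)
  frac <- colSums(counts[is_mito, , drop = FALSE]) / pmax(tot, 1)
  stats::setNames(frac, colnames(counts))
}

#' Single-cell RNA-seq cell quality control
#'
#' Three single-pass filters, each evaluated on the full input cohort:
#' \describe{
#'   \item{low_gene_count}{the number of detectable genes falls below the
#'     boxplot lower limit, Tukey's Q1 - 1.5 IQR, of the cohort.}
#'   \item{high_mito}{the fraction of fragments assigned to mitochondrial
#'     genes exceeds `mito_threshold` (strictly; exactly at the threshold
#'     passes).}
#'   \item{pca_outlier}{evaluated only on cells passing the first two
#'     filters: the cell's Euclidean distance from the centroid in the
#'     first two principal components of size-factor-normalised log1p
#'     counts (of those surviving cells) lies more than `mad_multiplier`
#'     median absolute deviations above the median of the surviving
#'     cells' distances. Cells already failed carry `pca_distance = NA`
#'     and `pca_outlier = FALSE`.}
#' }
#'
#' The PCA pass is sequential because cells with a collapsed or
#' mitochondria-dominated transcriptome are, by construction, extreme in
#' PCA space; evaluating the distance rule on the full cohort would
#' re-flag them and distort the distance distribution for the rest.
#'
#' @param counts Integer genes x cells matrix (at least 4 cells).
#' @param annotation Gene annotation data frame (`gene_id`, `is_mito`,
#'   `length_bp`).
#' @param mito_threshold Mitochondrial-fraction cutoff.
#' @param mad_multiplier PCA-distance cutoff in MADs.
#' @return Data frame `cell_id`, `n_detected_genes`, `mito_fraction`,
#'   `pca_distance`, `low_gene_count`, `high_mito`, `pca_outlier`,
#'   `pass`, `fail_reasons` (semicolon-joined, empty when passing).
#' @export
cell_qc <- function(counts, annotation, mito_threshold = 0.15,
                    mad_multiplier = 5) {
  if (ncol(counts) < 4) {
    stop("need at least 4 cells to evaluate the boxplot lower limit")
  }
  n_det <- detectable_genes(counts)
  q <- stats::quantile(n_det, c(0.25, 0.75), names = FALSE)
  lower_limit <- q[1] - 1.5 * (q[2] - q[1])
  low_gene_count <- n_det < lower_limit

  mito <- mito_fraction(counts, annotation)
  high_mito <- mito > mito_threshold

  # the PCA pass is sequential: only cells surviving the first two
  # filters enter the PCA and the distance rule
  surv <- which(!(low_gene_count | high_mito))
  dist <- rep(NA_real_, ncol(counts))
  pca_outlier <- rep(FALSE, ncol(counts))
  if (length(surv) >= 4) {
    sc <- counts[, surv, drop = FALSE]
    sf <- tryCatch(size_factors(sc),
                   error = function(e) size_factors(sc,
                                                    pseudocount = TRUE))
    norm <- log1p(sweep(sc, 2, sf, "/"))
    # identical cells leave nothing for PCA; every distance is then 0
    d <- tryCatch(sqrt(rowSums(pca_expr(t(norm), 2)$scores^2)),
                  error = function(e) numeric(length(surv)))
    dist[surv] <- d
    # robust outlier rule: a cell sits more than `mad_multiplier` MADs
    # beyond the typical centroid distance
    pca_outlier[surv] <- d > stats::median(d) +
      mad_multiplier * stats::mad(d)
  }

  fail <- cbind(low_gene_count, high_mito, pca_outlier)
  reasons <- apply(fail, 1, function(r) {
    paste(c("low_gene_count", "high_mito", "pca_outlier")[r],
          collapse = ";")
  })
  data.frame(cell_id = colnames(counts),
             n_detected_genes = unname(n_det),
             mito_fraction = unname(mito),
             pca_distance = unname(dist),
             low_gene_count = unname(low_gene_count),
             high_mito = unname(high_mito),
             pca_outlier = unname(pca_outlier),
             pass = unname(rowSums(fail) == 0),
             fail_reasons = unname(reasons),
             stringsAsFactors = FALSE)
}

#' Fragments per kilobase per million assigned fragments
#'
#' `fpkm[g, c] = count[g, c] / (length_kb[g] * total_count[c] / 1e6)`,
#' with gene lengths taken from the annotation and each cell's total
#' assigned fragments as the per-million denominator.
#'
#' @param counts Integer genes x cells matrix.
#' @param annotation Gene annotation data frame covering all genes.
#' @return Numeric genes x cells FPKM matrix.
#' @export
fpkm <- function(counts, annotation) {
  missing <- setdiff(rownames(counts), annotation$gene_id)
  if (length(missing) > 0) {
    stop("annotation missing genes: ", paste(missing, collapse = ", "))
  }
  len_kb <- annotation$length_bp[match(rownames(counts),
                                       annotation$gene_id)] / 1000
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("cell with zero total counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(counts / len_kb, 2, tot / 1e6, "/")
}

#' Rule set for the differential-expression post-filter
#'
#' @param min_detect_fraction A gene must be detectable in more than this
#'   fraction of cells in at least one group.
#' @param min_mean_fpkm ... at a mean FPKM above this in that same group.
#' @param direction_concordance Require the change in detection fraction
#'   and the change in mean expression to point the same way.
#' @return List of class `de_filter_rule`.
#' @export
de_filter_rule <- function(min_detect_fraction = 0.10, min_mean_fpkm = 1,
                           direction_concordance = TRUE) {
  stopifnot(min_detect_fraction >= 0, min_detect_fraction <= 1)
  structure(list(min_detect_fraction = min_detect_fraction,
                 min_mean_fpkm = min_mean_fpkm,
                 direction_concordance = direction_concordance),
            class = "de_filter_rule")
}

#' Post-filter a differential-expression table
#'
#' A significant gene is retained only if (a) in at least one group it is
#' detectable in more than `min_detect_fraction` of cells at a mean FPKM
#' above `min_mean_fpkm` (strict inequalities), and (b) the direction of
#' change in detection fraction matches the direction of change in mean
#' expression between the two groups; zero differences fail concordance.
#'
#' @param de_table Data frame with columns `gene_id`, `significant`
#'   (logical), `detect_frac_a`, `detect_frac_b`, `mean_fpkm_a`,
#'   `mean_fpkm_b`.
#' @param rule A [de_filter_rule()].
#' @return `de_table` with an added logical column `retained`.
#' @export
de_post_filter <- function(de_table, rule = de_filter_rule()) {
  need <- c("gene_id", "significant", "detect_frac_a", "detect_frac_b",
            "mean_fpkm_a", "mean_fpkm_b")
  missing <- setdiff(need, names(de_table))
  if (length(missing) > 0) {
    stop("de_table missing columns: ", paste(missing, collapse = ", "))
  }
  abundant <-
    (de_table$detect_frac_a > rule$min_detect_fraction &
       de_table$mean_fpkm_a > rule$min_mean_fpkm) |
    (de_table$detect_frac_b > rule$min_detect_fraction &
       de_table$mean_fpkm_b > rule$min_mean_fpkm)
  d_frac <- de_table$detect_frac_a - de_table$detect_frac_b
  d_mean <- de_table$mean_fpkm_a - de_table$mean_fpkm_b
  concordant <- sign(d_frac) == sign(d_mean) & d_frac != 0
  keep <- de_table$significant & abundant
  if (rule$direction_concordance) keep <- keep & concordant
  de_table$retained <- keep
  de_table
}

#' Two-group rank-sum significance flags (synthetic stand-in)
#'
#' A deliberately simple per-gene two-group Wilcoxon rank-sum test with
#' Benjamini-Hochberg correction, provided so that synthetic end-to-end
#' runs can feed [de_post_filter()] with a `significant` column. It is a
#' labelled stand-in for a dedicated single-cell differential-expression
#' method, not a recommendation.
#'
#' @param counts Integer genes x cells matrix.
#' @param groups Two-level factor over cells.
#' @param fdr FDR threshold for the flag.
#' @return Data frame `gene_id`, `p`, `q`, `significant`.
#' @export
de_flag_ranksum <- function(counts, groups, fdr = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  a <- counts[, groups == levels(groups)[1], drop = FALSE]
  b <- counts[, groups == levels(groups)[2], drop = FALSE]
  p <- vapply(seq_len(nrow(counts)), function(i) {
    if (stats::sd(counts[i, ]) == 0) return(1)
    suppressWarnings(stats::wilcox.test(a[i, ], b[i, ],
                                        exact = FALSE)$p.value)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(counts), p = p, q = q,
             significant = q < fdr, stringsAsFactors = FALSE)
}

#' Correlation between pooled single-cell and bulk expression
#'
#' Single-cell values are averaged across cells per gene and correlated
#' (Pearson) with per-gene bulk values over the shared gene set.
#'
#' @param single_expr Numeric genes x cells matrix (FPKM or expression).
#' @param bulk_expr Named numeric vector of per-gene bulk values.
#' @return List with `r`, `p.value`, `n_genes`.
#' @export
pooled_vs_bulk_corr <- function(single_expr, bulk_expr) {
  shared <- intersect(rownames(single_expr), names(bulk_expr))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  pooled <- rowMeans(single_expr[shared, , drop = FALSE])
  ct <- stats::cor.test(pooled, bulk_expr[shared])
  list(r = unname(ct$estimate), p.value = ct$p.value,
       n_genes = length(shared))
}
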