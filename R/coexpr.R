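#' Pairwise Pearson correlation between panel genes
#'
#' Correlations are computed on the LOD-anchored expression scale (see
#' [to_expression()]) over all supplied wells, or on binary detection
#' calls when `mode = "detection"` (the phi coefficient). Pairs where
#' either gene has zero variance are undefined and reported as `NA`.
#'
#' @param expr Numeric wells x genes matrix (expression or 0/1 calls).
#' @param genes Genes to correlate; default all columns.
#' @return Symmetric correlation matrix with `NA` for undefined pairs.
#' @export
pairwise_corr <- function(expr, genes = colnames(expr)) {
  if (nrow(expr) < 3) stop("need at least 3 wells")
  missing <- setdiff(genes, colnames(expr))
  if (length(missing) > 0) {
    stop("genes absent: ", paste(missing, collapse = ", "))
  }
  m <- expr[, genes, drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  r
}

# all permutations of 1..n (n small), one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Pearson r of fixed x against many column-permuted copies of y
corr_against_perms <- function(x, y, perm_idx) {
  yp <- matrix(y[perm_idx], nrow = length(y))
  as.vector(suppressWarnings(stats::cor(x, yp)))
}

#' Permutation test for pairwise marker co-expression
#'
#' For each gene pair the observed Pearson correlation is compared with an
#' empirical null built by randomly permuting the second gene's values
#' across wells (10,000 permutations by default). The two-tailed empirical
#' p-value uses the add-one rule, `p = (1 + #{|r_perm| >= |r_obs|}) /
#' (1 + n_perm)`, so p is floored at `1/(n_perm + 1)`; p-values are then
#' Benjamini-Hochberg adjusted across all evaluable pairs. With
#' `exhaustive = TRUE` every permutation of the wells is enumerated (only
#' feasible for very few wells) and the p-value is the exact fraction
#' `#{|r_perm| >= |r_obs|} / n!`.
#'
#' @param expr Numeric wells x genes matrix (see [to_expression()]); with
#'   `mode = "detection"` it is binarised as `expr > 0` first.
#' @param pairs Two-column character matrix or data frame of gene pairs.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutation draw.
#' @param mode `"expression"` (Pearson on the continuous scale) or
#'   `"detection"` (phi coefficient on 0/1 calls).
#' @param exhaustive Enumerate all permutations instead of sampling
#'   (requires at most 8 wells).
#' @return Data frame `gene_a`, `gene_b`, `r_obs`, `p_emp`, `q`,
#'   `n_perm`, `evaluable`, plus attributes `seed` and `mode`.
#' @export
perm_corr_test <- function(expr, pairs, n_perm = 10000, seed = 1,
                           mode = c("expression", "detection"),
                           exhaustive = FALSE) {
  mode <- match.arg(mode)
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, n_perm >= 1)
  missing <- setdiff(unique(as.vector(pairs)), colnames(expr))
  if (length(missing) > 0) {
    stop("genes absent: ", paste(missing, collapse = ", "))
  }
  m <- if (mode == "detection") (expr > 0) + 0 else expr
  n <- nrow(m)
  if (exhaustive) {
    if (n > 8) stop("exhaustive mode supports at most 8 wells")
    perm_idx <- t(all_permutations(n))
    n_used <- ncol(perm_idx)
  }
  set.seed(seed)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- m[, pairs[i, 1]]
    y <- m[, pairs[i, 2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      res[[i]] <- data.frame(gene_a = pairs[i, 1], gene_b = pairs[i, 2],
                             r_obs = NA_real_, p_emp = NA_real_,
                             n_perm = NA_integer_, evaluable = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    r_obs <- stats::cor(x, y)
    if (exhaustive) {
      r_perm <- corr_against_perms(x, y, perm_idx)
      p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
      np <- n_used
    } else {
      idx <- replicate(n_perm, sample.int(n))
      r_perm <- corr_against_perms(x, y, idx)
      p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (1 + n_perm)
      np <- n_perm
    }
    res[[i]] <- data.frame(gene_a = pairs[i, 1], gene_b = pairs[i, 2],
                           r_obs = r_obs, p_emp = p, n_perm = np,
                           evaluable = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q <- NA_real_
  out$q[out$evaluable] <- stats::p.adjust(out$p_emp[out$evaluable],
                                          method = "BH")
  out <- out[, c("gene_a", "gene_b", "r_obs", "p_emp", "q", "n_perm",
                 "evaluable")]
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  out
}

#' Principal component analysis of single-cell expression
#'
#' Centred (not variance-scaled) PCA. The sign of each component is fixed
#' by forcing its largest-magnitude gene loading to be positive, so scores
#' are reproducible across platforms.
#'
#' @param expr Numeric wells x genes matrix.
#' @param n_components Number of components to return.
#' @return List with `scores` (wells x components), `loadings` (genes x
#'   components) and `var_explained` (fraction of total variance per
#'   returned component).
#' @export
pca_expr <- function(expr, n_components = 2) {
  if (nrow(expr) < 2 || ncol(expr) < 2) {
    stop("need at least 2 wells and 2 genes")
  }
  fit <- stats::prcomp(expr, center = TRUE, scale. = FALSE)
  if (sum(fit$sdev^2) < .Machine$double.eps) {
    stop("matrix has no variance")
  }
  k <- min(n_components, ncol(fit$rotation))
  load <- fit$rotation[, seq_len(k), drop = FALSE]
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = load,
       var_explained = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)])
}

#' Centroid-distance Wilcoxon test for cluster separation
#'
#' Quantifies whether two labelled groups of points separate in the first
#' two principal components: for every point, its Euclidean distance to
#' its own group's centroid is compared with its distance to the pooled
#' centroid of both groups. If the groups are truly separated, points sit
#' systematically closer to their own centroid, and a paired two-sided
#' Wilcoxon signed-rank test over all points (zero differences dropped)
#' detects this. An unpaired rank-sum variant is available via
#' `paired = FALSE`.
#'
#' @param scores Numeric points x components matrix (at least 2 columns);
#'   only the first two components are used.
#' @param labels Two-group factor or character vector, one per point.
#' @param paired Use the paired signed-rank reading (default) or a
#'   rank-sum test of the two distance sets.
#' @return List with `d_own`, `d_pooled` (per-point distances),
#'   `statistic`, `p.value`, `test`.
#' @export
cluster_separation_test <- function(scores, labels, paired = TRUE) {
  s <- as.matrix(scores)[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) stop("exactly two groups required")
  if (any(table(labels) < 3)) {
    stop("each group needs at least 3 points")
  }
  pooled <- colMeans(s)
  d_pooled <- sqrt(rowSums(sweep(s, 2, pooled)^2))
  d_own <- numeric(nrow(s))
  for (g in groups) {
    rows <- labels == g
    cen <- colMeans(s[rows, , drop = FALSE])
    d_own[rows] <- sqrt(rowSums(sweep(s[rows, , drop = FALSE], 2, cen)^2))
  }
  if (paired) {
    nz <- d_own != d_pooled
    if (sum(nz) == 0) stop("all own/pooled distances tie; test undefined")
    wt <- suppressWarnings(
      stats::wilcox.test(d_own[nz], d_pooled[nz], paired = TRUE,
                         exact = FALSE)
    )
    test <- "wilcoxon-signed-rank-paired"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d_own, d_pooled,
                                              exact = FALSE))
    test <- "wilcoxon-rank-sum"
  }
  list(d_own = d_own, d_pooled = d_pooled,
       statistic = unname(wt$statistic), p.value = wt$p.value,
       test = test)
}
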