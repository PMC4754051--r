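test_that("detectability is one-fragment based", {
  m <- matrix(c(0, 1, 5, 0, 0, 0), 3, 2,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  nd <- detectable_genes(m)
  expect_equal(unname(nd), c(2, 0))
  expect_equal(unname(nd), unname(colSums(m != 0)))
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(2, 4, 4, 8), 2, 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  sf <- size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)

  ident <- matrix(7, 5, 4, dimnames = list(paste0("g", 1:5),
                                           paste0("c", 1:4)))
  expect_equal(unname(size_factors(ident)), rep(1, 4))

  # scale equivariance: scaling one cell scales its factor relative to
  # the others (the shared geometric means absorb a global constant)
  set.seed(2)
  r <- matrix(stats::rpois(200, 20) + 1, 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  sf0 <- size_factors(r)
  r2 <- r
  r2[, 3] <- r2[, 3] * 5
  sf1 <- size_factors(r2)
  expect_equal(unname((sf1[3] / sf1[1]) / (sf0[3] / sf0[1])), 5)

  # brute-force re-computation on a random matrix: per-cell median of
  # count/geomean ratios, the median taken on the log scale
  set.seed(9)
  rr <- matrix(stats::rnbinom(500, mu = 30, size = 5), 50, 10,
               dimnames = list(paste0("g", 1:50), paste0("c", 1:10)))
  ok <- rowSums(rr > 0) == 10
  geo <- exp(rowMeans(log(rr[ok, ])))
  brute <- apply(rr[ok, ], 2,
                 function(col) exp(stats::median(log(col / geo))))
  expect_equal(unname(size_factors(rr)), unname(brute))

  zero <- matrix(c(0, 1, 1, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_error(size_factors(zero), "pseudocount")
  expect_true(all(size_factors(zero, pseudocount = TRUE) > 0))
})

test_that("size factors agree with an established implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(14)
  m <- matrix(stats::rnbinom(600, mu = 50, size = 8), 60, 10,
              dimnames = list(paste0("g", 1:60), paste0("c", 1:10)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("planted true size factors are recovered from simulation", {
  sim <- simulate_counts(n_cells = 50, n_genes = 1000, mito_genes = 13,
                         seed = 33)
  est <- size_factors(sim$counts)
  truth <- sim$truth$size_factors
  ratio <- est / truth
  rel <- ratio / stats::median(ratio)
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("cell QC flags exactly the planted failure modes", {
  sim <- simulate_counts(n_cells = 40, n_genes = 500, mito_genes = 10,
                         planted_outliers = 4,
                         outlier_type = c("mito", "mito", "mito",
                                          "low_complexity"),
                         seed = 12)
  qc <- cell_qc(sim$counts, sim$annotation)
  expect_identical(which(qc$high_mito), 1:3)
  expect_true(qc$low_gene_count[4])
  expect_false(any(qc$low_gene_count[5:40]))
  expect_identical(qc$pass, !(qc$low_gene_count | qc$high_mito |
                                qc$pca_outlier))
  expect_true(all(qc$fail_reasons[qc$pass] == ""))
  expect_true(grepl("high_mito", qc$fail_reasons[1]))
})

test_that("QC boundaries and degenerate inputs behave as specified", {
  sim <- simulate_counts(n_cells = 10, n_genes = 100, mito_genes = 5,
                         seed = 6)
  # a cell sitting exactly at mito fraction 0.15 passes (strict >)
  counts <- sim$counts
  mito <- startsWith(rownames(counts), "MT-")
  counts[mito, 1] <- 0L
  counts[which(mito)[1], 1] <- 3L
  counts[!mito, 1] <- 0L
  counts[which(!mito)[1:17], 1] <- 1L
  frac <- mito_fraction(counts, sim$annotation)[1]
  expect_equal(unname(frac), 0.15)
  qc <- cell_qc(counts, sim$annotation)
  expect_false(qc$high_mito[1])

  # identical (non-mitochondrial) cells can produce no outliers
  ident <- matrix(5L, 20, 10,
                  dimnames = list(sim$annotation$gene_id[6:25],
                                  paste0("c", 1:10)))
  qc2 <- cell_qc(ident, sim$annotation)
  expect_true(all(qc2$pass))
  expect_error(cell_qc(sim$counts[, 1:3], sim$annotation),
               "at least 4 cells")
})

test_that("cell QC verdicts are stable under reordering", {
  sim <- simulate_counts(n_cells = 25, n_genes = 300, mito_genes = 8,
                         planted_outliers = 2, seed = 18)
  qc <- cell_qc(sim$counts, sim$annotation)
  set.seed(1)
  gp <- sample(nrow(sim$counts))
  cp <- sample(ncol(sim$counts))
  qc2 <- cell_qc(sim$counts[gp, cp], sim$annotation)
  qc2 <- qc2[match(qc$cell_id, qc2$cell_id), ]
  expect_equal(qc2$fail_reasons, qc$fail_reasons)
})

test_that("FPKM has the right units and conserves totals", {
  counts <- matrix(c(100L, 900L), 2, 1,
                   dimnames = list(c("g1", "g2"), "c1"))
  anno <- data.frame(gene_id = c("g1", "g2"), is_mito = FALSE,
                     length_bp = c(1000, 2000))
  counts2 <- counts
  counts2["g1", 1] <- 999900L  # bring the library to 1e6
  counts2["g2", 1] <- 100L
  f <- fpkm(counts2, anno)
  expect_equal(unname(f["g1", 1]), 999900 / 1)
  # doubling a gene's length halves its FPKM
  anno2 <- anno
  anno2$length_bp[1] <- 2000
  expect_equal(fpkm(counts2, anno2)["g1", 1] * 2, f["g1", 1])
  # conservation: sum(fpkm * len_kb) * total / 1e6 = total
  sim <- simulate_counts(n_cells = 5, n_genes = 50, mito_genes = 3,
                         seed = 4)
  fs <- fpkm(sim$counts, sim$annotation)
  len_kb <- sim$annotation$length_bp / 1000
  tot <- colSums(sim$counts)
  expect_equal(unname(colSums(fs * len_kb) * tot / 1e6), unname(tot))

  bad <- sim$counts
  bad[, 2] <- 0L
  expect_error(fpkm(bad, sim$annotation), "zero total")
})

test_that("DE post-filter enforces abundance and concordance gates", {
  tab <- data.frame(
    gene_id = c("both_down", "discordant", "too_rare", "flat",
                "not_sig"),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    detect_frac_a = c(0.5, 0.5, 0.05, 0.4, 0.5),
    detect_frac_b = c(0.1, 0.1, 0.08, 0.4, 0.1),
    mean_fpkm_a = c(10, 1, 0.5, 5, 10),
    mean_fpkm_b = c(1, 10, 0.9, 2, 1)
  )
  out <- de_post_filter(tab)
  expect_identical(out$retained,
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # raising the FPKM gate never adds genes
  strict <- de_post_filter(tab, de_filter_rule(min_mean_fpkm = 20))
  expect_true(all(out$retained | !strict$retained))
  expect_error(de_post_filter(tab[, -2]), "missing columns")
})

test_that("pooled single-cell means correlate with matching bulk", {
  sim <- simulate_counts(n_cells = 20, n_genes = 90, mito_genes = 5,
                         seed = 25)
  fs <- fpkm(sim$counts, sim$annotation)
  pooled <- rowMeans(fs)
  expect_equal(pooled_vs_bulk_corr(fs, pooled)$r, 1)
  affine <- 3 * pooled + 7
  expect_equal(pooled_vs_bulk_corr(fs, affine)$r, 1)
  set.seed(2)
  noisy <- pooled * exp(stats::rnorm(90, 0, 0.8))
  r <- pooled_vs_bulk_corr(fs, noisy)$r
  expect_true(r > 0.3 && r < 1)
  expect_error(pooled_vs_bulk_corr(fs[1:2, ], pooled[1:2]), "3 shared")
})
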