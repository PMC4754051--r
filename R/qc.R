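#' Call per-well, per-gene detection from Ct values
#'
#' A gene counts as detectably expressed in a well when its Ct lies
#' strictly below the limit of detection (default 30 cycles); the
#' no-amplification sentinel never detects.
#'
#' @param x A [ct_matrix()].
#' @param lod Limit of detection in cycles.
#' @return List of class `detection_matrix`: `detected` (logical wells x
#'   genes), `lod`, and the per-well `batch` labels carried over.
#' @export
#' @examples
#' m <- matrix(c(29.99, 30), 1, dimnames = list("A", c("g1", "g2")))
#' call_detection(ct_matrix(m))$detected
call_detection <- function(x, lod = 30) {
  stopifnot(inherits(x, "ct_matrix"), lod > 0)
  structure(list(detected = x$ct < lod, lod = lod, batch = x$batch),
            class = "detection_matrix")
}

#' Housekeeper-based well quality control
#'
#' A well is taken to contain a successfully reverse transcribed cell iff
#' the housekeeper GAPDH is detected. Returns the retained wells and a
#' per-well report.
#'
#' @param det A `detection_matrix` from [call_detection()].
#' @param housekeeper Gene whose detection defines a valid well.
#' @return List with `valid_wells` (character), `report` (data frame
#'   `well_id`, `batch`, `pass`).
#' @export
well_qc <- function(det, housekeeper = "GAPDH") {
  stopifnot(inherits(det, "detection_matrix"))
  if (!housekeeper %in% colnames(det$detected)) {
    stop("housekeeper gene ", housekeeper, " absent from the panel")
  }
  pass <- det$detected[, housekeeper]
  report <- data.frame(well_id = rownames(det$detected),
                       batch = unname(det$batch),
                       pass = unname(pass),
                       stringsAsFactors = FALSE)
  list(valid_wells = rownames(det$detected)[pass], report = report)
}

#' Adjust Ct values across chips by housekeeper differences
#'
#' For each chip (batch) the shift is the mean, over the housekeeping
#' genes GAPDH and ACTB, of the difference between the gene's mean
#' detected Ct on that chip and on the reference chip; only QC-passing
#' wells enter the means. The shift is subtracted from every non-sentinel
#' entry of the chip, so the reference chip is returned unchanged.
#'
#' @param x A [ct_matrix()].
#' @param reference_batch Chip label used as anchor; defaults to the first
#'   chip in order of appearance.
#' @param housekeepers Genes anchoring the adjustment.
#' @param lod Limit of detection used for the underlying detection calls.
#' @return List with `ct` (adjusted [ct_matrix()]) and `adjustment` (data
#'   frame `batch`, `shift`, plus attributes `reference_batch`,
#'   `housekeepers`).
#' @export
batch_adjust <- function(x, reference_batch = NULL,
                         housekeepers = c("GAPDH", "ACTB"), lod = 30) {
  stopifnot(inherits(x, "ct_matrix"))
  batches <- unique(unname(x$batch))
  if (is.null(reference_batch)) reference_batch <- batches[1]
  if (!reference_batch %in% batches) {
    stop("reference batch ", reference_batch, " not present")
  }
  missing_hk <- setdiff(housekeepers, gene_ids(x))
  if (length(missing_hk) > 0) {
    stop("housekeeper genes absent: ", paste(missing_hk, collapse = ", "))
  }
  det <- call_detection(x, lod)
  qc <- well_qc(det, housekeeper = housekeepers[1])
  keep <- rownames(x$ct) %in% qc$valid_wells

  mean_hk <- function(b) {
    rows <- keep & x$batch == b
    vapply(housekeepers, function(g) {
      v <- x$ct[rows, g]
      v <- v[v < lod]
      if (length(v) == 0) {
        stop("batch ", b, ": housekeeper ", g,
             " not detected in any QC-passing well")
      }
      mean(v)
    }, numeric(1))
  }
  ref_means <- mean_hk(reference_batch)
  shifts <- vapply(batches, function(b) {
    if (b == reference_batch) return(0)
    mean(mean_hk(b) - ref_means)
  }, numeric(1))

  adj <- x$ct
  for (b in batches) {
    rows <- x$batch == b
    sub <- adj[rows, , drop = FALSE]
    nonsent <- sub != CT_SENTINEL
    sub[nonsent] <- sub[nonsent] - shifts[[b]]
    adj[rows, ] <- sub
  }
  adjustment <- data.frame(batch = batches, shift = unname(shifts),
                           stringsAsFactors = FALSE)
  attr(adjustment, "reference_batch") <- reference_batch
  attr(adjustment, "housekeepers") <- housekeepers
  list(ct = ct_matrix(adj, x$batch), adjustment = adjustment)
}

#' Inter-chip technical-replicate reliability per gene
#'
#' The same single-cell cDNA run on two chips should give near-identical
#' Ct profiles; genes that do not reproduce are excluded from downstream
#' analysis. For each shared gene the squared Pearson correlation is
#' computed over shared wells with non-sentinel values on both chips;
#' genes with fewer than `min_pairs` such wells are reported as not
#' evaluable.
#'
#' @param ct_a,ct_b [ct_matrix()] objects for the two chips.
#' @param min_pairs Minimum paired detections for an r-squared.
#' @param threshold Genes with r-squared below this are flagged as
#'   unreliable.
#' @return Data frame `gene_id`, `n_pairs`, `r_squared`, `evaluable`,
#'   `unreliable`.
#' @export
replicate_reliability <- function(ct_a, ct_b, min_pairs = 3,
                                  threshold = 0.5) {
  stopifnot(inherits(ct_a, "ct_matrix"), inherits(ct_b, "ct_matrix"))
  wells <- intersect(well_ids(ct_a), well_ids(ct_b))
  if (length(wells) == 0) stop("no shared wells between the two chips")
  genes <- intersect(gene_ids(ct_a), gene_ids(ct_b))
  a <- ct_a$ct[wells, genes, drop = FALSE]
  b <- ct_b$ct[wells, genes, drop = FALSE]
  res <- lapply(genes, function(g) {
    ok <- a[, g] != CT_SENTINEL & b[, g] != CT_SENTINEL
    n <- sum(ok)
    r2 <- NA_real_
    if (n >= min_pairs &&
        stats::sd(a[ok, g]) > 0 && stats::sd(b[ok, g]) > 0) {
      r2 <- stats::cor(a[ok, g], b[ok, g])^2
    }
    data.frame(gene_id = g, n_pairs = n, r_squared = r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$evaluable <- !is.na(out$r_squared)
  out$unreliable <- out$evaluable & out$r_squared < threshold
  out
}

#' Dilution-series linearity per gene
#'
#' Checks linear amplification: Ct should rise linearly with log2
#' dilution. For each gene, the r-squared of the least-squares line of Ct
#' on log2 dilution is computed over detected points only.
#'
#' @param ct_series A [ct_matrix()] with one row per dilution point.
#' @param log2_dilutions Numeric vector, one log2 dilution per row.
#' @param lod Limit of detection.
#' @param min_points Minimum detected points for a fit.
#' @return Data frame `gene_id`, `n_points`, `r_squared`, `evaluable`.
#' @export
dilution_linearity <- function(ct_series, log2_dilutions, lod = 30,
                               min_points = 3) {
  stopifnot(inherits(ct_series, "ct_matrix"))
  if (length(log2_dilutions) != nrow(ct_series$ct)) {
    stop("one log2 dilution per row required")
  }
  if (length(log2_dilutions) < 3) stop("need at least 3 dilution points")
  res <- lapply(gene_ids(ct_series), function(g) {
    y <- ct_series$ct[, g]
    ok <- y < lod
    n <- sum(ok)
    r2 <- NA_real_
    if (n >= min_points && stats::sd(y[ok]) > 0 &&
        stats::sd(log2_dilutions[ok]) > 0) {
      r2 <- stats::cor(y[ok], log2_dilutions[ok])^2
    }
    data.frame(gene_id = g, n_points = n, r_squared = r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$evaluable <- !is.na(out$r_squared)
  out
}

#' Transform Ct values to a LOD-anchored expression scale
#'
#' Ct is inversely related to abundance, so expression is taken as
#' `lod - ct` for detected entries and 0 otherwise. This keeps undetected
#' (censored) reactions in the analysis as zeros on a monotone scale; the
#' alternative of correlating binary detection calls is available in the
#' co-expression functions.
#'
#' @param x A [ct_matrix()].
#' @param lod Limit of detection in cycles.
#' @return Numeric wells x genes matrix of non-negative expression values,
#'   with attribute `lod`.
#' @export
#' @examples
#' m <- matrix(c(20, 999), 1, dimnames = list("A", c("g1", "g2")))
#' to_expression(ct_matrix(m))
to_expression <- function(x, lod = 30) {
  stopifnot(inherits(x, "ct_matrix"), lod > 0)
  expr <- pmax(lod - x$ct, 0)
  expr[x$ct >= lod] <- 0
  attr(expr, "lod") <- lod
  expr
}
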