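#' Read a gene x cell count matrix
#'
#' Two on-disk layouts are supported: a TSV with gene ids in the first
#' column and one column per cell, or a MatrixMarket triplet file with
#' sidecar id files (`<path>` plus `<path>.genes` and `<path>.cells`, one
#' id per line, `path` typically ending in `.mtx`).
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @return Integer matrix (genes x cells) with dimnames.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- genes
  } else {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".genes"))
    cells <- readLines(paste0(path, ".cells"))
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop("sidecar id files do not match matrix dimensions")
    }
    dimnames(m) <- list(genes, cells)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; the `mtx` format writes the MatrixMarket
#' triplet plus `.genes` / `.cells` sidecars.
#'
#' @param counts Integer matrix (genes x cells) with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(is.matrix(counts), !is.null(dimnames(counts)))
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes"))
    writeLines(colnames(counts), paste0(path, ".cells"))
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `is_mito` (0/1) and `length_bp`. When
#' `genes` is supplied, every listed gene must be annotated.
#'
#' @param path Path to the annotation TSV.
#' @param genes Optional character vector of gene ids that must be covered.
#' @return Data frame with columns `gene_id`, `is_mito` (logical) and
#'   `length_bp`.
#' @export
read_gene_annotation <- function(path, genes = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("gene_id", "is_mito", "length_bp")
  if (!all(need %in% names(df))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (any(df$length_bp <= 0)) stop("length_bp must be positive")
  df$is_mito <- as.logical(df$is_mito)
  if (!is.null(genes)) {
    missing <- setdiff(genes, df$gene_id)
    if (length(missing) > 0) {
      stop("annotation missing genes: ", paste(missing, collapse = ", "))
    }
  }
  df[, need]
}

#' Write a gene annotation table
#'
#' @param annotation Data frame with columns `gene_id`, `is_mito`,
#'   `length_bp`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  out <- data.frame(gene_id = annotation$gene_id,
                    is_mito = as.integer(annotation$is_mito),
                    length_bp = annotation$length_bp)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
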