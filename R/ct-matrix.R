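#' Sentinel Ct value for failed amplification
#'
#' Wells in which a gene never crosses the fluorescence threshold carry no
#' cycle-threshold value; exports encode these reactions with the sentinel
#' 999 (the convention also used for "Undetermined" or empty cells when
#' reading tables).
#'
#' @export
CT_SENTINEL <- 999

#' Construct a cycle-threshold matrix
#'
#' The raw currency of the qPCR half of the package: one row per well, one
#' column per assayed gene, entries in cycles with [CT_SENTINEL] marking no
#' amplification, plus a per-well chip (batch) label.
#'
#' @param ct Numeric matrix (wells x genes) with row and column names.
#' @param batch Character vector of per-well chip labels, recycled if length
#'   one. Defaults to `"batch1"`.
#' @return An object of class `ct_matrix`: a list with elements `ct`
#'   (the matrix) and `batch` (named character vector).
#' @export
#' @examples
#' m <- matrix(c(25, 999), 1, 2, dimnames = list("A1", c("GAPDH", "MAP2")))
#' ct_matrix(m)
ct_matrix <- function(ct, batch = "batch1") {
  stopifnot(is.matrix(ct), is.numeric(ct))
  if ((nrow(ct) > 0 && is.null(rownames(ct))) || is.null(colnames(ct))) {
    stop("ct matrix needs well ids as rownames and gene ids as colnames")
  }
  if (anyDuplicated(rownames(ct))) stop("duplicate well ids")
  if (anyDuplicated(colnames(ct))) stop("duplicate gene ids")
  bad <- ct[is.finite(ct)]
  if (any(bad <= 0 & bad != CT_SENTINEL) || any(bad > CT_SENTINEL)) {
    stop("Ct entries must be the sentinel ", CT_SENTINEL,
         " or lie in (0, ", CT_SENTINEL, ")")
  }
  batch <- rep_len(as.character(batch), nrow(ct))
  names(batch) <- rownames(ct)
  structure(list(ct = ct, batch = batch), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d wells x %d genes, %d batch(es)\n",
              nrow(x$ct), ncol(x$ct), length(unique(x$batch))))
  det <- mean(x$ct < CT_SENTINEL)
  cat(sprintf("  amplified entries: %.1f%%\n", 100 * det))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

well_ids <- function(x) {
  if (is.null(rownames(x$ct))) character(0) else rownames(x$ct)
}
gene_ids <- function(x) colnames(x$ct)

# strings treated as "no amplification" on input
SENTINEL_STRINGS <- c("999", "", "NA", "Undetermined", "undetermined")

parse_ct_values <- function(values, where) {
  out <- rep(NA_real_, length(values))
  values <- trimws(values)
  is_sent <- values %in% SENTINEL_STRINGS | is.na(values)
  out[is_sent] <- CT_SENTINEL
  num <- suppressWarnings(as.numeric(values[!is_sent]))
  if (anyNA(num)) {
    bad <- which(!is_sent)[which(is.na(num))[1]]
    stop("non-numeric Ct value ", dQuote(values[bad]), " at ", where[bad])
  }
  out[!is_sent] <- num
  out
}

#' Read a Ct table from CSV
#'
#' Two dialects are accepted. `wide` (the canonical Biomark-export-like
#' layout): a header of gene symbols, one row per well, an optional `batch`
#' column; the first column holds well ids. `long`: columns `well`, `gene`,
#' `ct` and optionally `batch`. In either dialect the strings `"999"`,
#' `"Undetermined"`, `"NA"` and empty cells are normalised to the
#' no-amplification sentinel.
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (dialect == "wide") {
    id_col <- names(df)[1]
    wells <- df[[id_col]]
    if (anyDuplicated(wells)) {
      stop("duplicate well id in ", path, ": ",
           wells[duplicated(wells)][1])
    }
    batch <- if ("batch" %in% names(df)) df$batch else "batch1"
    genes <- setdiff(names(df), c(id_col, "batch"))
    ct <- matrix(NA_real_, length(wells), length(genes),
                 dimnames = list(wells, genes))
    for (g in genes) {
      ct[, g] <- parse_ct_values(df[[g]],
                                 sprintf("row %d, gene %s", seq_along(wells), g))
    }
    ct_matrix(ct, batch)
  } else {
    need <- c("well", "gene", "ct")
    if (!all(need %in% names(df))) {
      stop("long dialect needs columns well, gene, ct")
    }
    key <- paste(df$well, df$gene, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1, ]
      stop("duplicate (well, gene) pair: (", d$well, ", ", d$gene, ")")
    }
    vals <- parse_ct_values(df$ct, sprintf("row %d", seq_len(nrow(df))))
    wells <- unique(df$well)
    genes <- unique(df$gene)
    ct <- matrix(CT_SENTINEL, length(wells), length(genes),
                 dimnames = list(wells, genes))
    ct[cbind(match(df$well, wells), match(df$gene, genes))] <- vals
    batch <- rep("batch1", length(wells))
    if ("batch" %in% names(df)) {
      batch <- df$batch[match(wells, df$well)]
    }
    ct_matrix(ct, batch)
  }
}

#' Write a Ct table to CSV
#'
#' Lossless inverse of [read_ct_table()]: sentinel entries are written as
#' the literal `999`.
#'
#' @param x A [ct_matrix()].
#' @param path Output CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "ct_matrix"))
  fmt <- function(v) sprintf("%.17g", v)  # round-trips doubles exactly
  if (dialect == "wide") {
    df <- data.frame(well_id = well_ids(x), batch = unname(x$batch),
                     check.names = FALSE)
    for (g in gene_ids(x)) df[[g]] <- fmt(x$ct[, g])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(
      well = rep(well_ids(x), times = ncol(x$ct)),
      gene = rep(gene_ids(x), each = nrow(x$ct)),
      ct = fmt(as.vector(x$ct)),
      batch = rep(unname(x$batch), times = ncol(x$ct))
    )
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
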