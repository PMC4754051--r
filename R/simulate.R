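#' Configuration for the single-cell qPCR simulator
#'
#' Describes a sorted-plate experiment: how many wells, the mixture of cell
#' archetypes across wells, per-gene detection efficiency in truly
#' expressing cells, the Ct level and spread of detected reactions,
#' per-chip batch offsets and the GABAergic fraction among neurons.
#'
#' Archetypes: `deep-neuron`, `upper-neuron`, `mixed-neuron` (expresses
#' both deep- and upper-layer markers), `markerless-neuron` (pan-neuronal
#' markers only), `glia`, and `failed-well` (no successfully reverse
#' transcribed cell; nothing amplifies, in particular not GAPDH).
#'
#' The defaults mirror the category frequencies of a typical
#' iPSC-derived cortical culture sorted at >81 days: ~15% failed wells,
#' ~5% non-neuronal cells, and neurons split between single, mixed and
#' absent layer identity, with ~24% of neurons GABAergic.
#'
#' @param n_wells Number of sorted wells.
#' @param composition Named numeric vector of archetype proportions,
#'   summing to one.
#' @param p_detect Per-gene probability that a truly expressing gene is
#'   detected (amplifies below the limit of detection); scalar or named
#'   vector over panel genes. `1` switches dropout off.
#' @param mean_ct_on Mean Ct of detected reactions (cycles).
#' @param ct_sd Ct standard deviation of detected reactions (cycles).
#' @param batch_shifts Named numeric vector of additive per-chip Ct
#'   offsets; wells are assigned to chips in rotation.
#' @param gaba_fraction Proportion of neurons expressing GAD1.
#' @param seed Integer seed making the simulation reproducible.
#' @return A list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(n_wells = 478,
                            composition = c("deep-neuron" = 0.210,
                                            "upper-neuron" = 0.170,
                                            "mixed-neuron" = 0.180,
                                            "markerless-neuron" = 0.235,
                                            "glia" = 0.055,
                                            "failed-well" = 0.150),
                            p_detect = 0.85,
                            mean_ct_on = 20,
                            ct_sd = 2,
                            batch_shifts = c(chip1 = 0),
                            gaba_fraction = 0.239,
                            seed = 1) {
  archetypes <- c("deep-neuron", "upper-neuron", "mixed-neuron",
                  "markerless-neuron", "glia", "failed-well")
  if (length(n_wells) != 1 || n_wells <= 0 || n_wells != round(n_wells)) {
    stop("n_wells must be a positive integer")
  }
  if (is.null(names(composition)) ||
      !all(names(composition) %in% archetypes)) {
    stop("composition must be named with archetypes: ",
         paste(archetypes, collapse = ", "))
  }
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition proportions must sum to 1 (got ",
         format(sum(composition)), ")")
  }
  if (any(composition < 0)) stop("composition proportions must be >= 0")
  if (any(p_detect < 0 | p_detect > 1)) stop("p_detect must lie in [0, 1]")
  if (is.null(names(batch_shifts))) stop("batch_shifts must be named")
  structure(list(n_wells = as.integer(n_wells), composition = composition,
                 p_detect = p_detect, mean_ct_on = mean_ct_on,
                 ct_sd = ct_sd, batch_shifts = batch_shifts,
                 gaba_fraction = gaba_fraction, seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

# largest-remainder apportionment: integer counts matching proportions
apportion <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

# gene sets truly expressed by each archetype
archetype_programs <- function(panel) {
  genes <- panel_genes()
  neg_ctrl <- c("ALB", "UMOD")
  glial_bg <- c("GFAP", "OLIG2", "ALDH1L1", "AQP4", "S100B", "MBP",
                "PDGFRA", "CSPG4", "VIM", "TNC", "HES1", "HES5",
                "NOTCH1", "SOX2", "NES", "PTPRZ1")
  marker_all <- unlist(panel, use.names = FALSE)
  neuron_bg <- setdiff(genes, c(marker_all, neg_ctrl, glial_bg))
  neuron_base <- c(panel$housekeepers, panel$neuron, neuron_bg)
  list(
    "deep-neuron" = c(neuron_base, panel$deep),
    "upper-neuron" = c(neuron_base, panel$upper),
    "mixed-neuron" = c(neuron_base, panel$deep, panel$upper),
    "markerless-neuron" = neuron_base,
    "glia" = c(panel$housekeepers, setdiff(glial_bg, c("SOX2", "NES"))),
    "failed-well" = character(0)
  )
}

#' Simulate a single-cell qPCR Ct matrix with known ground truth
#'
#' Draws wells from the archetype mixture of `config`, builds each well's
#' true expression program from the marker panel, applies per-gene
#' detection dropout, and fills detected entries with Gaussian Ct values
#' (mean `mean_ct_on` plus the well's chip offset, sd `ct_sd`, truncated
#' below zero). Everything else carries the no-amplification sentinel.
#' Failed wells amplify nothing, so they are GAPDH-negative and fail well
#' QC downstream.
#'
#' @param config A [qpcr_sim_config()].
#' @param panel A [marker_panel()].
#' @return List with elements `ct` (a [ct_matrix()]) and `truth`: a list
#'   with `wells` (data frame `well_id`, `archetype`, `batch`, `is_gaba`)
#'   and `expressing` (logical wells x genes matrix of true expression).
#' @export
#' @examples
#' sim <- simulate_qpcr(qpcr_sim_config(n_wells = 50, seed = 7))
#' table(sim$truth$wells$archetype)
simulate_qpcr <- function(config = qpcr_sim_config(),
                          panel = marker_panel()) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  set.seed(config$seed)
  genes <- panel_genes()
  n <- config$n_wells

  counts <- apportion(config$composition, n)
  labels <- sample(rep(names(config$composition), counts))
  chips <- rep_len(names(config$batch_shifts), n)
  well_id <- sprintf("W%04d", seq_len(n))

  programs <- archetype_programs(panel)
  expressing <- matrix(FALSE, n, length(genes),
                       dimnames = list(well_id, genes))
  for (i in seq_len(n)) expressing[i, programs[[labels[i]]]] <- TRUE

  is_neuron <- labels %in% c("deep-neuron", "upper-neuron",
                             "mixed-neuron", "markerless-neuron")
  is_gaba <- is_neuron & stats::runif(n) < config$gaba_fraction
  expressing[, panel$gaba] <- is_gaba
  expressing[, panel$glut] <- is_neuron & !is_gaba

  p_detect <- rep_len(config$p_detect, length(genes))
  if (!is.null(names(config$p_detect))) {
    p_detect <- rep(1, length(genes))
    names(p_detect) <- genes
    p_detect[names(config$p_detect)] <- config$p_detect
  }
  detect_prob <- matrix(p_detect, n, length(genes), byrow = TRUE)
  detected <- expressing & (stats::runif(n * length(genes)) < detect_prob)

  shift <- config$batch_shifts[chips]
  ct <- matrix(CT_SENTINEL, n, length(genes),
               dimnames = list(well_id, genes))
  k <- sum(detected)
  if (k > 0) {
    # per-entry chip shift: expand by row
    row_of <- row(detected)[detected]
    vals <- stats::rnorm(k, config$mean_ct_on + shift[row_of], config$ct_sd)
    ct[detected] <- pmax(vals, 0.01)
  }

  truth <- list(
    wells = data.frame(well_id = well_id, archetype = labels,
                       batch = chips, is_gaba = is_gaba,
                       stringsAsFactors = FALSE),
    expressing = expressing
  )
  list(ct = ct_matrix(ct, chips), truth = truth)
}

#' Deterministic worked-example fixture
#'
#' Builds, with no randomness, a 478-well Ct matrix whose classification
#' marginals match a reference single-cell RT-qPCR characterisation of
#' iPSC-derived cortical neurons: 406 GAPDH-positive wells (85.3%), 380 of
#' them neurons (93.6%), of which 184 carry markers of exactly one layer
#' class (split here 100 deep-only / 84 upper-only; only the aggregate is
#' constrained), 85 carry both deep and upper markers (mixed identity),
#' 111 carry no layer marker, and 91 express GAD1 (23.9%). Detected
#' entries are fixed at Ct 20; everything else is the sentinel.
#'
#' @return List with elements `ct` (a [ct_matrix()]) and `truth` (as in
#'   [simulate_qpcr()], with the extra archetype label `non-neuron` for
#'   GAPDH-positive wells without neuronal markers).
#' @export
#' @examples
#' fx <- worked_example_fixture()
#' nrow(fx$ct$ct)
worked_example_fixture <- function() {
  genes <- panel_genes()
  n <- 478L
  well_id <- sprintf("W%03d", seq_len(n))
  ct <- matrix(CT_SENTINEL, n, length(genes),
               dimnames = list(well_id, genes))

  archetype <- c(rep("failed-well", 72),
                 rep("non-neuron", 26),
                 rep("deep-neuron", 100),
                 rep("upper-neuron", 84),
                 rep("mixed-neuron", 85),
                 rep("markerless-neuron", 111))
  ok <- archetype != "failed-well"
  ct[ok, "GAPDH"] <- 20
  ct[ok, "ACTB"] <- 20
  neuron <- grepl("neuron$", archetype) & archetype != "non-neuron"
  ct[neuron, "MAP2"] <- 20
  ct[archetype == "deep-neuron", "BCL11B"] <- 20
  ct[archetype == "upper-neuron", "CUX1"] <- 20
  ct[archetype == "mixed-neuron", "TBR1"] <- 20
  ct[archetype == "mixed-neuron", "SATB2"] <- 20
  is_gaba <- logical(n)
  is_gaba[which(neuron)[seq_len(91)]] <- TRUE
  ct[is_gaba, "GAD1"] <- 20
  ct[neuron & !is_gaba, "SLC17A7"] <- 20

  expressing <- ct < CT_SENTINEL
  truth <- list(
    wells = data.frame(well_id = well_id, archetype = archetype,
                       batch = "chip1", is_gaba = is_gaba,
                       stringsAsFactors = FALSE),
    expressing = expressing
  )
  list(ct = ct_matrix(ct, "chip1"), truth = truth)
}

#' Simulate a single-cell RNA-seq count matrix with known ground truth
#'
#' Negative-binomial counts around log-normal gene means, scaled by
#' per-cell true size factors drawn uniformly from `size_factor_range`.
#' The first `mito_genes` genes are mitochondrial (named `MT-*`) and are
#' calibrated so that a typical cell assigns ~5% of its fragments to
#' them. Planted outlier cells (the first `planted_outliers` columns)
#' receive a mitochondrial fraction around 0.5 (`"mito"`), have 90% of
#' their non-mitochondrial genes zeroed out (`"low_complexity"`), or both.
#' Gene lengths are drawn uniformly in 0.5-10 kb and recorded in the
#' annotation.
#'
#' @param n_cells,n_genes Dimensions of the matrix.
#' @param mito_genes Number of mitochondrial genes (< `n_genes`).
#' @param size_factor_range Length-2 positive interval for true size
#'   factors.
#' @param planted_outliers Number of planted outlier cells.
#' @param outlier_type `"mito"`, `"low_complexity"` or `"both"`, recycled
#'   over the planted cells.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return List with `counts` (integer genes x cells matrix),
#'   `annotation` (data frame `gene_id`, `is_mito`, `length_bp`) and
#'   `truth` (list: `size_factors`, `outlier` logical per cell,
#'   `outlier_type` per cell, `NA` for unplanted cells).
#' @export
simulate_counts <- function(n_cells, n_genes, mito_genes = 13,
                            size_factor_range = c(0.5, 2),
                            planted_outliers = 0,
                            outlier_type = "both",
                            dispersion = 10,
                            seed = 1) {
  if (n_cells <= 0 || n_genes <= 0) stop("dimensions must be positive")
  if (mito_genes >= n_genes) stop("mito_genes must be < n_genes")
  if (any(size_factor_range <= 0)) stop("size factors must be positive")
  if (planted_outliers > n_cells) stop("more outliers than cells")
  set.seed(seed)

  gene_id <- c(sprintf("MT-%d", seq_len(mito_genes)),
               sprintf("G%04d", seq_len(n_genes - mito_genes)))
  is_mito <- startsWith(gene_id, "MT-")

  # deep full-length libraries: high mean coverage per expressed gene
  mu <- exp(stats::rnorm(n_genes, log(100), 1.5))
  # calibrate mitochondrial load to ~5% of assigned fragments
  mu[is_mito] <- mu[is_mito] *
    (0.05 / 0.95) * sum(mu[!is_mito]) / sum(mu[is_mito])
  sf <- stats::runif(n_cells, size_factor_range[1], size_factor_range[2])

  counts <- matrix(stats::rnbinom(n_genes * n_cells,
                                  mu = outer(mu, sf),
                                  size = dispersion),
                   n_genes, n_cells,
                   dimnames = list(gene_id, sprintf("C%04d", seq_len(n_cells))))

  type <- rep(NA_character_, n_cells)
  if (planted_outliers > 0) {
    type[seq_len(planted_outliers)] <-
      rep_len(outlier_type, planted_outliers)
    for (j in seq_len(planted_outliers)) {
      if (type[j] %in% c("low_complexity", "both")) {
        # collapse gene count; scale the mitochondrial load alongside so
        # the mitochondrial fraction stays at its baseline
        nm <- which(!is_mito)
        drop <- sample(nm, floor(0.9 * length(nm)))
        counts[drop, j] <- 0L
        counts[is_mito, j] <- round(0.1 * counts[is_mito, j])
      }
      if (type[j] %in% c("mito", "both")) {
        m <- sum(counts[is_mito, j])
        r <- sum(counts[!is_mito, j])
        if (m > 0) counts[is_mito, j] <- round(counts[is_mito, j] * r / m)
      }
    }
  }
  storage.mode(counts) <- "integer"

  annotation <- data.frame(
    gene_id = gene_id, is_mito = is_mito,
    length_bp = round(stats::runif(n_genes, 500, 10000)),
    stringsAsFactors = FALSE
  )
  truth <- list(size_factors = stats::setNames(sf, colnames(counts)),
                outlier = !is.na(type), outlier_type = type)
  list(counts = counts, annotation = annotation, truth = truth)
}
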