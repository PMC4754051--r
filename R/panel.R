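#' The default 96-gene single-cell RT-qPCR panel
#'
#' Gene symbols for the multiplex qPCR panel used throughout the package:
#' phenotype and cortical-layer marker genes, genes related to neuronal and
#' synaptic function, progenitor and glial genes, two housekeeping genes
#' (GAPDH, ACTB) and two negative-control genes normally expressed only in
#' liver or kidney (ALB, UMOD).
#'
#' @return Character vector of 96 unique gene symbols.
#' @export
#' @examples
#' length(panel_genes())
panel_genes <- function() {
  genes <- c(
    # housekeepers and phenotype / layer markers
    "GAPDH", "ACTB",
    "MAP2", "NCAM1", "TUBB3",
    "BCL11B", "TBR1",
    "CUX1", "POU3F2", "SATB2",
    "GAD1", "SLC17A7",
    "GFAP", "OLIG2",
    # glutamatergic receptor and synaptic genes
    "GRIA1", "GRIA2", "GRIA3", "GRIN1", "GRIN2A", "GRIN2B",
    "DLG4", "SYN1", "ANK2", "SNAP25", "SYT1", "SYP",
    "DLG1", "HOMER1", "SHANK3", "NLGN1", "CAMK2A",
    # neocortical identity and development
    "FEZF2", "NEUROD6", "ADAMTS3", "FEZF1", "POU3F3",
    "TLE4", "FOXP2", "RORB", "ETV1", "OTX1", "SOX5",
    "NFIA", "NFIB", "LHX2", "EMX2", "FOXG1", "PAX6", "EOMES",
    # migration, guidance, cytoskeleton
    "DCX", "ROBO2", "NRXN1", "MAP1B", "CDK5R1", "RELN",
    "NRCAM", "L1CAM", "CNTN2", "EFNB2", "EPHA4", "SEMA3A",
    "PLXNA1", "STMN2", "GAP43",
    # channels, neurotrophins, interneuron subtypes
    "CACNA1C", "KCNQ2", "SCN1A", "SCN2A", "BDNF", "NTRK2",
    "GABRA1", "GABRB2", "SLC17A6", "SLC32A1",
    "CALB1", "CALB2", "PVALB", "SST", "VIP", "NPY",
    # glial and progenitor genes
    "PTPRZ1", "ALDH1L1", "AQP4", "S100B", "MBP", "PDGFRA",
    "CSPG4", "VIM", "TNC", "HES1", "HES5", "NOTCH1",
    "SOX2", "NES",
    # negative controls (liver / kidney restricted)
    "ALB", "UMOD"
  )
  stopifnot(length(genes) == 96L, !anyDuplicated(genes))
  genes
}

#' Marker panel used for phenotype and cortical-layer classification
#'
#' Defines which genes of the qPCR panel carry classification weight:
#' pan-neuronal markers, deep-layer and upper-layer transcription factors,
#' the GABAergic and glutamatergic markers, glial markers and the
#' housekeeping genes used for well QC and batch anchoring.
#'
#' @param neuron,deep,upper,gaba,glut,glia,housekeepers Character vectors of
#'   gene symbols overriding the defaults. The marker classes must be
#'   mutually disjoint.
#' @return A list of class `marker_panel` with components `neuron`, `deep`,
#'   `upper`, `gaba`, `glut`, `glia` and `housekeepers`.
#' @export
#' @examples
#' marker_panel()$deep
marker_panel <- function(neuron = c("MAP2", "NCAM1", "TUBB3"),
                         deep = c("BCL11B", "TBR1"),
                         upper = c("CUX1", "POU3F2", "SATB2"),
                         gaba = "GAD1",
                         glut = "SLC17A7",
                         glia = c("GFAP", "OLIG2"),
                         housekeepers = c("GAPDH", "ACTB")) {
  panel <- list(neuron = neuron, deep = deep, upper = upper,
                gaba = gaba, glut = glut, glia = glia,
                housekeepers = housekeepers)
  all_genes <- unlist(panel, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    stop("marker classes must be disjoint; duplicated: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  }
  structure(panel, class = "marker_panel")
}

# internal: error unless every panel gene is a column of the matrix
check_panel_genes <- function(panel, gene_ids) {
  missing <- setdiff(unlist(panel, use.names = FALSE), gene_ids)
  if (length(missing) > 0) {
    stop("marker panel genes absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
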