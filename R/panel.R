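#' The bundled 158-gene in situ sequencing panel
#'
#' Returns the ordered vector of gene symbols probed by the targeted panel
#' used throughout this package. The panel targets neuronal subtype markers
#' (excitatory, inhibitory, immature), glial markers, and activity- and
#' disease-related genes in the mouse hippocampal formation.
#'
#' Upstream documentation of the assay mentions both 158 and 159 probes in
#' different places; the bundled list is the 158-symbol panel and the
#' discrepancy is flagged here rather than resolved.
#'
#' @param path Optional path to a plain-text panel file (one symbol per
#'   line). Defaults to the bundled panel.
#' @return Character vector of unique gene symbols (length 158 for the
#'   bundled panel).
#' @export
#' @examples
#' panel <- gene_panel()
#' length(panel)
gene_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_panel_158.txt", package = "hippotx",
                        mustWork = TRUE)
  }
  genes <- readLines(path, warn = FALSE)
  genes <- genes[nzchar(trimws(genes))]
  genes <- trimws(genes)
  if (anyDuplicated(genes)) {
    stop("gene panel contains duplicated symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  genes
}

#' Marker rule set for divisive hierarchical cell typing
#'
#' Loads the marker rules that define the seven-way cell-type partition
#' (immature, excitatory, inhibitory neurons; astrocytes, microglia,
#' oligodendrocytes; other). Rules are expressed as positive/negative gene
#' requirements over the targeted panel; see [classify_cells()] for the
#' cascade semantics.
#'
#' @param path Optional path to a JSON rule file. Defaults to the bundled
#'   rule set.
#' @param panel Gene panel used to validate that every rule gene is probed.
#' @return A list of class `marker_rules` with components
#'   `neuron_exclusion`, `immature_positive`, `immature_alt_positive`,
#'   `immature_alt_negative`, `pan_neuronal`, `inhibitory_markers`, and the
#'   astro/micro/oligo gating genes.
#' @export
marker_rules <- function(path = NULL, panel = gene_panel()) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_rules.json", package = "hippotx",
                        mustWork = TRUE)
  }
  rules <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("neuron_exclusion", "immature_positive", "immature_alt_positive",
              "immature_alt_negative", "pan_neuronal", "inhibitory_markers",
              "astro_positive", "astro_negative", "micro_positive",
              "micro_negative", "oligo_positive", "oligo_negative")
  missing <- setdiff(needed, names(rules))
  if (length(missing)) {
    stop("marker rule file missing fields: ", paste(missing, collapse = ", "))
  }
  rule_genes <- unique(unlist(rules[needed], use.names = FALSE))
  off_panel <- setdiff(rule_genes, panel)
  if (length(off_panel)) {
    stop("rule genes not on the panel: ", paste(off_panel, collapse = ", "))
  }
  structure(rules[needed], class = "marker_rules")
}

#' @export
print.marker_rules <- function(x, ...) {
  cat("<marker_rules>\n")
  cat("  neuron exclusion genes: ", length(x$neuron_exclusion), "\n", sep = "")
  cat("  pan-neuronal genes:     ", length(x$pan_neuronal), "\n", sep = "")
  cat("  inhibitory markers:     ", length(x$inhibitory_markers), "\n", sep = "")
  invisible(x)
}

#' The seven cell-type labels produced by the classifier
#' @return Character vector of labels in cascade order.
#' @export
cell_type_levels <- function() {
  c("immature", "excitatory", "inhibitory",
    "astrocyte", "microglia", "oligodendrocyte", "other")
}

#' The four experimental groups
#'
#' C/T = corn oil (vehicle) vs tamoxifen (enhanced newborn-neuron survival
#' via inducible Bax deletion); NB = Nestin-CreERT2;Bax fl/fl, NBF = NB
#' crossed to the 5XFAD familial Alzheimer's model.
#' @return Character vector of group labels.
#' @export
group_levels <- function() c("C-NB", "T-NB", "C-NBF", "T-NBF")

#' Hippocampal-formation region labels
#' @return Character vector of region names (SGL is a flag on DG membership,
#'   not a separate exclusive region).
#' @export
region_levels <- function() c("CA1", "CA2", "CA3", "DG", "SGL", "EC")
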