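#' Percent expression per stratum
#'
#' Percent expression of a gene in a stratum is 100 x (number of cells
#' with count >= the positivity threshold) / (cells in the stratum) — the
#' statistic all differential expression in this package is computed on.
#'
#' @param cells A classified `cell_matrix`.
#' @param genes Genes to report (default: whole panel).
#' @param by Per-cell metadata columns defining the strata (default cell
#'   type, region, group).
#' @param min_spots_positive Positivity threshold.
#' @return Tibble with the grouping columns, `gene`, `n_cells`, `n_pos`,
#'   `pct` (0-100; `NA` for an empty stratum never occurs here because
#'   strata are taken from the data).
#' @export
percent_expression <- function(cells, genes = NULL,
                               by = c("cell_type", "region", "group"),
                               min_spots_positive = 1) {
  pos <- positivity_matrix(cells, min_spots_positive)
  if (is.null(genes)) genes <- rownames(pos)
  meta <- cells$cells
  stopifnot(all(by %in% names(meta)))
  key <- do.call(paste, c(meta[by], sep = "\r"))
  idx <- split(seq_len(ncol(pos)), key)
  rows <- purrr::imap(idx, function(cols, k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    npos <- Matrix::rowSums(pos[genes, cols, drop = FALSE])
    out <- tibble::as_tibble(stats::setNames(as.list(parts), by))
    out <- out[rep(1, length(genes)), ]
    out$gene <- genes
    out$n_cells <- length(cols)
    out$n_pos <- as.integer(unname(npos))
    out$pct <- 100 * unname(npos) / length(cols)
    out
  })
  dplyr::bind_rows(rows)
}

#' Pseudovalue log2 fold change of percent expression
#'
#' `log2((pct1 + s) / (pct2 + s))`, where the pseudovalue `s` guards
#' against infinite values when one side is zero. By convention `s` is the
#' minimum *nonzero* percent expression over all genes of the stratum pair
#' (a zero minimum would not prevent infinities); a fixed constant may be
#' supplied instead.
#'
#' @param pct1,pct2 Percent expression (0-100) in groups 1 and 2.
#' @param pseudovalue Positive pseudovalue `s`.
#' @return Numeric vector of log2 fold changes (antisymmetric in its
#'   arguments).
#' @export
log2_fold_change <- function(pct1, pct2, pseudovalue) {
  stopifnot(pseudovalue > 0, all(pct1 >= 0 & pct1 <= 100, na.rm = TRUE),
            all(pct2 >= 0 & pct2 <= 100, na.rm = TRUE))
  log2((pct1 + pseudovalue) / (pct2 + pseudovalue))
}

min_nonzero_pseudovalue <- function(pcts) {
  nz <- pcts[!is.na(pcts) & pcts > 0]
  if (!length(nz)) {
    warning("all percent expressions are zero; pseudovalue undefined")
    return(NA_real_)
  }
  min(nz)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH FDR adjustment; `NA` p-values propagate as `NA` and are
#' excluded from the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

direction_call <- function(log2fc, fc_threshold = 1.5) {
  dplyr::case_when(
    is.na(log2fc) ~ NA_character_,
    log2fc > log2(fc_threshold) ~ "up",
    log2fc < -log2(fc_threshold) ~ "down",
    TRUE ~ "ns"
  )
}

# Core per-stratum DEG given positivity counts for the two groups.
deg_core <- function(genes, pos1, n1, pos2, n2, comparison,
                     fc_threshold = 1.5, pseudovalue = "min_nonzero") {
  pos1 <- unname(pos1); pos2 <- unname(pos2)
  pct1 <- 100 * pos1 / n1
  pct2 <- 100 * pos2 / n2
  s <- if (identical(pseudovalue, "min_nonzero")) {
    min_nonzero_pseudovalue(c(pct1, pct2))
  } else {
    stopifnot(is.numeric(pseudovalue), pseudovalue > 0)
    pseudovalue
  }
  res <- purrr::map(seq_along(genes), function(i) {
    tab <- matrix(c(pos1[i], n1 - pos1[i], pos2[i], n2 - pos2[i]), nrow = 2)
    ft <- stats::fisher.test(tab)
    c(or = unname(ft$estimate), p = ft$p.value)
  })
  or <- purrr::map_dbl(res, "or")
  p <- pmin(purrr::map_dbl(res, "p"), 1)  # guard tiny floating excess over 1
  lfc <- if (is.na(s)) rep(NA_real_, length(genes)) else
    log2_fold_change(pct1, pct2, s)
  tibble::tibble(
    gene = genes, comparison = comparison,
    n1 = n1, n2 = n2, pos1 = as.integer(pos1), pos2 = as.integer(pos2),
    pct1 = pct1, pct2 = pct2, pseudovalue = s,
    odds_ratio = or, p = p, q = bh_fdr(p),
    log2fc = lfc, direction = direction_call(lfc, fc_threshold)
  )
}

#' Percent-expression differential expression by Fisher's exact test
#'
#' For one cell type, region, and pair of groups: builds, per panel gene,
#' the 2x2 table of cells expressing / not expressing the gene in each
#' group (cells pooled within group), computes the two-sided Fisher exact
#' p (summation of table probabilities <= the observed one) and
#' conditional-MLE odds ratio, applies BH FDR across the panel genes
#' within this stratum, and reports the pseudovalue log2 fold change of
#' percent expression with up/down calls at |FC| > `fc_threshold`.
#'
#' @param cells A classified `cell_matrix`.
#' @param cell_type One of [cell_type_levels()], or `"neuron"` for mature
#'   neurons (excitatory plus inhibitory).
#' @param region Region label.
#' @param group_pair Character vector `c(group1, group2)`; fold changes
#'   are group1 relative to group2.
#' @param min_spots_positive Positivity threshold.
#' @param fc_threshold Fold-change cutoff for the direction call.
#' @param pseudovalue `"min_nonzero"` (default) or a fixed positive
#'   constant.
#' @return Tibble, one row per panel gene, with counts, `odds_ratio`, `p`,
#'   `q`, `log2fc`, `direction`, plus `cell_type` and `region`; `NULL`
#'   with a message when either group has no cells in the stratum.
#' @export
fisher_deg <- function(cells, cell_type, region, group_pair,
                       min_spots_positive = 1, fc_threshold = 1.5,
                       pseudovalue = "min_nonzero") {
  stopifnot(length(group_pair) == 2)
  meta <- cells$cells
  type_ok <- if (identical(cell_type, "neuron")) {
    meta$cell_type %in% c("excitatory", "inhibitory")
  } else {
    meta$cell_type == cell_type
  }
  sel1 <- which(type_ok & meta$region == region & meta$group == group_pair[1])
  sel2 <- which(type_ok & meta$region == region & meta$group == group_pair[2])
  if (!length(sel1) || !length(sel2)) {
    message("stratum ", cell_type, "/", region, " skipped: empty group")
    return(NULL)
  }
  pos <- positivity_matrix(cells, min_spots_positive)
  genes <- rownames(pos)
  out <- deg_core(genes,
                  Matrix::rowSums(pos[, sel1, drop = FALSE]), length(sel1),
                  Matrix::rowSums(pos[, sel2, drop = FALSE]), length(sel2),
                  comparison = paste(group_pair, collapse = "/"),
                  fc_threshold = fc_threshold, pseudovalue = pseudovalue)
  out$cell_type <- cell_type
  out$region <- region
  dplyr::relocate(out, "cell_type", "region")
}

#' Pairwise DEG across cell types, regions, and comparisons
#'
#' Orchestrates [fisher_deg()] over the requested strata. FDR scope
#' `"stratum"` (default) corrects across the panel genes within each
#' (cell type, region, comparison); `"global"` recomputes q across all
#' returned rows.
#'
#' @param cells A classified `cell_matrix`.
#' @param cell_types,regions Strata to cover.
#' @param pairs List of 2-vectors of group labels (default: the study's
#'   three comparisons).
#' @param fdr_scope `"stratum"` or `"global"`.
#' @inheritParams fisher_deg
#' @return Combined DEG tibble.
#' @export
deg_pairwise <- function(cells,
                         cell_types = "neuron",
                         regions = c("CA1", "CA2", "CA3", "DG", "EC"),
                         pairs = default_comparisons(),
                         fdr_scope = c("stratum", "global"),
                         min_spots_positive = 1, fc_threshold = 1.5,
                         pseudovalue = "min_nonzero") {
  fdr_scope <- match.arg(fdr_scope)
  grid <- tidyr::expand_grid(cell_type = cell_types, region = regions,
                             pair = pairs)
  out <- purrr::pmap(grid, function(cell_type, region, pair) {
    fisher_deg(cells, cell_type, region, pair,
               min_spots_positive = min_spots_positive,
               fc_threshold = fc_threshold, pseudovalue = pseudovalue)
  })
  out <- dplyr::bind_rows(out)
  if (fdr_scope == "global" && nrow(out)) out$q <- bh_fdr(out$p)
  out
}

#' The study's default pairwise group comparisons
#' @return List of group pairs: C-NB/C-NBF, T-NBF/C-NBF, T-NB/C-NB.
#' @export
default_comparisons <- function() {
  list(c("C-NB", "C-NBF"), c("T-NBF", "C-NBF"), c("T-NB", "C-NB"))
}

#' Layer-stratified DEG in the entorhinal cortex
#'
#' As [fisher_deg()] but with strata (cell type, EC layer), using the
#' upper/lower labels from [estimate_ec_layers()].
#'
#' @param cells A classified `cell_matrix`.
#' @param layer_labels Tibble with `cell_id`, `layer` (from
#'   [estimate_ec_layers()], possibly several samples bound together).
#' @param cell_type Cell type (or `"neuron"`).
#' @param group_pair Character vector of two groups.
#' @inheritParams fisher_deg
#' @return DEG tibble with a `layer` column (one block per layer).
#' @export
layer_deg <- function(cells, layer_labels, cell_type, group_pair,
                      min_spots_positive = 1, fc_threshold = 1.5,
                      pseudovalue = "min_nonzero") {
  meta <- cells$cells
  lay <- layer_labels$layer[match(meta$cell_id, layer_labels$cell_id)]
  type_ok <- if (identical(cell_type, "neuron")) {
    meta$cell_type %in% c("excitatory", "inhibitory")
  } else {
    meta$cell_type == cell_type
  }
  pos <- positivity_matrix(cells, min_spots_positive)
  genes <- rownames(pos)
  out <- purrr::map(c("upper", "lower"), function(L) {
    sel1 <- which(type_ok & !is.na(lay) & lay == L & meta$group == group_pair[1])
    sel2 <- which(type_ok & !is.na(lay) & lay == L & meta$group == group_pair[2])
    if (!length(sel1) || !length(sel2)) {
      message("layer ", L, " skipped: empty group")
      return(NULL)
    }
    res <- deg_core(genes,
                    Matrix::rowSums(pos[, sel1, drop = FALSE]), length(sel1),
                    Matrix::rowSums(pos[, sel2, drop = FALSE]), length(sel2),
                    comparison = paste(group_pair, collapse = "/"),
                    fc_threshold = fc_threshold, pseudovalue = pseudovalue)
    res$cell_type <- cell_type
    res$layer <- L
    dplyr::relocate(res, "cell_type", "layer")
  })
  dplyr::bind_rows(out)
}
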