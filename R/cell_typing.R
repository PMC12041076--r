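positivity_matrix <- function(cells, min_spots_positive = 1) {
  # genes x cells logical matrix: "expressed" on a targeted panel
  cells$counts >= min_spots_positive
}

any_positive <- function(pos, genes) {
  genes <- intersect(genes, rownames(pos))
  if (!length(genes)) return(rep(FALSE, ncol(pos)))
  Matrix::colSums(pos[genes, , drop = FALSE]) > 0
}

#' Classify cells with the divisive hierarchical marker-rule cascade
#'
#' Assigns every cell exactly one of seven labels using a priori marker
#' rules over the targeted panel. Positivity means `count >=
#' min_spots_positive` (default 1 spot — the only reading consistent with
#' "expressed"/"negative" language on a targeted panel; exposed as a
#' parameter). The cascade:
#'
#' * neuron: negative for all twelve exclusion genes (glial, vascular,
#'   ependymal markers); everything else is a nonneuron;
#' * immature neuron: a neuron located in the SGL and positive for any of
#'   Dcx/Ncam1/Neurod1, or positive for Prox1 and negative for Rbfox3
#'   (the second clause is location-free by default; set
#'   `immature_requires_sgl_always = TRUE` for the stricter reading);
#' * mature neurons split into inhibitory (any pan-neuronal gene plus any
#'   of the 37 interneuron markers) and excitatory (the remainder);
#' * nonneurons gate astrocyte, microglia, oligodendrocyte in that order
#'   (the rules are mutually exclusive by construction), remainder "other".
#'
#' @param cells A `cell_matrix` with regions assigned (the `in_sgl` flag
#'   feeds the immature rule; if absent the location clause is skipped
#'   with a warning).
#' @param rules A [marker_rules()] rule set.
#' @param min_spots_positive Spot-count threshold for positivity.
#' @param immature_requires_sgl_always Require SGL residence for the
#'   Prox1+/Rbfox3- branch as well.
#' @return The `cell_matrix` with `cell_type` filled in.
#' @export
classify_cells <- function(cells, rules = marker_rules(),
                           min_spots_positive = 1,
                           immature_requires_sgl_always = FALSE) {
  pos <- positivity_matrix(cells, min_spots_positive)
  n <- ncol(pos)
  in_sgl <- cells$cells$in_sgl
  if (is.null(in_sgl) || all(is.na(in_sgl))) {
    warning("no SGL membership flag; immature location clause skipped")
    in_sgl <- rep(FALSE, n)
  }
  in_sgl[is.na(in_sgl)] <- FALSE

  neuron <- !any_positive(pos, rules$neuron_exclusion)
  prox1 <- any_positive(pos, rules$immature_alt_positive)
  rbfox3 <- any_positive(pos, rules$immature_alt_negative)
  clause1 <- in_sgl & any_positive(pos, rules$immature_positive)
  clause2 <- prox1 & !rbfox3
  if (immature_requires_sgl_always) clause2 <- clause2 & in_sgl
  immature <- neuron & (clause1 | clause2)
  mature <- neuron & !immature
  inhibitory <- mature & any_positive(pos, rules$pan_neuronal) &
    any_positive(pos, rules$inhibitory_markers)
  excitatory <- mature & !inhibitory

  astro <- !neuron & any_positive(pos, rules$astro_positive) &
    !any_positive(pos, rules$astro_negative)
  micro <- !neuron & any_positive(pos, rules$micro_positive) &
    !any_positive(pos, rules$micro_negative)
  oligo <- !neuron & any_positive(pos, rules$oligo_positive) &
    !any_positive(pos, rules$oligo_negative)
  other <- !neuron & !astro & !micro & !oligo

  label <- rep(NA_character_, n)
  label[immature] <- "immature"
  label[inhibitory] <- "inhibitory"
  label[excitatory] <- "excitatory"
  label[astro] <- "astrocyte"
  label[micro] <- "microglia"
  label[oligo] <- "oligodendrocyte"
  label[other] <- "other"
  stopifnot(!anyNA(label))
  cells$cells$cell_type <- label
  cells
}

#' Cell-type composition by stratum
#'
#' Counts and proportions of the seven cell types within each combination
#' of the grouping columns (default region x group). Strata named in
#' `regions`/`groups` but absent from the data are emitted as zero rows
#' with `proportion = NA`.
#'
#' @param cells A classified `cell_matrix`.
#' @param by Character vector of per-cell metadata columns to stratify by.
#' @param regions,groups Optional level sets to complete the table over.
#' @return Tibble with grouping columns, `cell_type`, `n`, `proportion`.
#' @export
type_composition <- function(cells, by = c("region", "group"),
                             regions = NULL, groups = NULL) {
  meta <- cells$cells
  stopifnot(all(by %in% names(meta)), !all(is.na(meta$cell_type)))
  tab <- meta |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), .data$cell_type,
                 name = "n")
  levels_of <- function(v) {
    if (v == "cell_type") return(cell_type_levels())
    if (v == "region" && !is.null(regions)) return(regions)
    if (v == "group" && !is.null(groups)) return(groups)
    unique(tab[[v]])
  }
  vars <- c(by, "cell_type")
  grid <- rlang::exec(tidyr::expand_grid,
                      !!!stats::setNames(lapply(vars, levels_of), vars))
  tab <- dplyr::left_join(grid, tab, by = c(by, "cell_type")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(total = sum(.data$n),
                  proportion = dplyr::if_else(.data$total > 0,
                                              .data$n / .data$total,
                                              NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::select(-"total")
  tab
}

#' Fisher test on the inhibitory fraction of mature neurons
#'
#' Compares the abundance of inhibitory vs excitatory profile neurons in a
#' region between two groups (cells pooled within group) with a two-sided
#' Fisher exact test on the 2x2 table.
#'
#' @param cells A classified `cell_matrix`.
#' @param region Region to test.
#' @param group_a,group_b The two groups (odds ratio is inhibitory odds in
#'   `group_a` relative to `group_b`).
#' @return One-row tibble: counts, conditional-MLE odds ratio, `log2_or`,
#'   two-sided `p`. NA with a warning when a table margin is empty.
#' @export
inhibitory_fraction_test <- function(cells, region, group_a, group_b) {
  meta <- cells$cells
  sub <- meta[meta$region == region & meta$group %in% c(group_a, group_b) &
                meta$cell_type %in% c("excitatory", "inhibitory"), ]
  a <- sum(sub$group == group_a & sub$cell_type == "inhibitory")
  c_ <- sum(sub$group == group_a & sub$cell_type == "excitatory")
  b <- sum(sub$group == group_b & sub$cell_type == "inhibitory")
  d <- sum(sub$group == group_b & sub$cell_type == "excitatory")
  out <- tibble::tibble(region = region, group_a = group_a,
                        group_b = group_b,
                        inh_a = a, exc_a = c_, inh_b = b, exc_b = d,
                        odds_ratio = NA_real_, log2_or = NA_real_,
                        p = NA_real_)
  if ((a + c_) == 0 || (b + d) == 0) {
    warning("empty group margin for ", region, "; returning NA")
    return(out)
  }
  ft <- stats::fisher.test(matrix(c(a, c_, b, d), nrow = 2))
  out$odds_ratio <- unname(ft$estimate)
  out$log2_or <- log2(unname(ft$estimate))
  out$p <- ft$p.value
  out
}
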