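#' Call restored and fully restored genes
#'
#' A gene is "restored" in T-NBF when it is significantly differentially
#' expressed in the T-NBF/C-NBF comparison (q < `alpha`) and its fold
#' change has the same (strictly nonzero) sign as in the C-NB/C-NBF
#' comparison — i.e. enhancing neurogenesis moved its expression in the
#' FAD background the same way the healthy baseline differs from FAD. It
#' is "fully restored" when the C-NB/C-NBF change is also significant at
#' `alpha`.
#'
#' @param deg_cnb DEG tibble for the C-NB/C-NBF comparison (from
#'   [fisher_deg()]/[deg_pairwise()]).
#' @param deg_tnbf DEG tibble for the T-NBF/C-NBF comparison over the same
#'   strata.
#' @param alpha Significance threshold on q (0.05 by default; 0.2 is used
#'   for some glial analyses — always an explicit parameter).
#' @return Tibble, one row per (gene, cell_type, region): `status` in
#'   restored / fully_restored / not_restored / NA (NA when the stratum is
#'   missing from either comparison), with the underlying q and log2fc
#'   values and the alpha used.
#' @export
call_restored <- function(deg_cnb, deg_tnbf, alpha = 0.05) {
  key <- c("gene", "cell_type", "region")
  stopifnot(all(key %in% names(deg_cnb)), all(key %in% names(deg_tnbf)))
  joined <- dplyr::full_join(
    dplyr::select(deg_tnbf, dplyr::all_of(key),
                  q_tnbf = "q", log2fc_tnbf = "log2fc"),
    dplyr::select(deg_cnb, dplyr::all_of(key),
                  q_cnb = "q", log2fc_cnb = "log2fc"),
    by = key
  )
  joined |>
    dplyr::mutate(
      sign_match = sign(.data$log2fc_tnbf) == sign(.data$log2fc_cnb) &
        .data$log2fc_tnbf != 0 & .data$log2fc_cnb != 0,
      status = dplyr::case_when(
        is.na(.data$q_tnbf) | is.na(.data$q_cnb) |
          is.na(.data$log2fc_tnbf) | is.na(.data$log2fc_cnb) ~ NA_character_,
        .data$q_tnbf < alpha & .data$sign_match &
          .data$q_cnb < alpha ~ "fully_restored",
        .data$q_tnbf < alpha & .data$sign_match ~ "restored",
        TRUE ~ "not_restored"
      ),
      alpha = alpha
    ) |>
    dplyr::select(-"sign_match")
}

#' Summarize restored-gene calls
#'
#' @param calls Output of [call_restored()].
#' @return List with `per_stratum` (counts of restored + fully restored
#'   genes per cell type and region) and `per_cell_type` (unique genes per
#'   cell type over the union of regions — a gene restored in two regions
#'   counts once here, twice in the per-region totals).
#' @export
restored_summary <- function(calls) {
  hits <- calls[!is.na(calls$status) &
                  calls$status %in% c("restored", "fully_restored"), ]
  per_stratum <- hits |>
    dplyr::count(.data$cell_type, .data$region, name = "n_restored")
  per_cell_type <- hits |>
    dplyr::distinct(.data$cell_type, .data$gene) |>
    dplyr::count(.data$cell_type, name = "n_unique_genes")
  list(per_stratum = per_stratum, per_cell_type = per_cell_type,
       n_total_unique = dplyr::n_distinct(hits$gene))
}

#' Fold-change consistency between comparisons
#'
#' Ordinary least squares of the C-NB/C-NBF log2 fold change (y) on the
#' T-NBF/C-NBF log2 fold change (x), per region over all genes, plus one
#' pooled fit restricted to genes with q < `filter_q` in at least one of
#' the two comparisons. A strong positive slope means enhanced
#' neurogenesis moved the FAD expression profile toward the healthy
#' baseline consistently across genes. Pearson's r is also reported since
#' it is orientation-free.
#'
#' @param deg_cnb,deg_tnbf DEG tibbles for the two comparisons (same cell
#'   type, matching strata).
#' @param filter_q q threshold for the pooled filtered fit (default 0.2).
#' @return Object of class `consistency_fit`: a tibble with one row per
#'   stratum (`slope`, `intercept`, `pearson_r`, `adj_r2`, `p_value`,
#'   `n_genes`); the underlying `lm` fits are kept in the `"models"`
#'   attribute. Strata with fewer than 3 paired genes yield NA fits.
#' @export
fc_consistency <- function(deg_cnb, deg_tnbf, filter_q = 0.2) {
  key <- c("gene", "cell_type", "region")
  paired <- dplyr::inner_join(
    dplyr::select(deg_tnbf, dplyr::all_of(key), x = "log2fc", q_x = "q"),
    dplyr::select(deg_cnb, dplyr::all_of(key), y = "log2fc", q_y = "q"),
    by = key
  )
  fit_one <- function(df, stratum) {
    df <- df[stats::complete.cases(df[, c("x", "y")]), ]
    if (nrow(df) < 3) {
      return(list(row = tibble::tibble(stratum = stratum, slope = NA_real_,
                                       intercept = NA_real_,
                                       pearson_r = NA_real_,
                                       adj_r2 = NA_real_, p_value = NA_real_,
                                       n_genes = nrow(df)),
                  model = NULL))
    }
    m <- stats::lm(y ~ x, data = df)
    sm <- summary(m)
    pv <- if (nrow(df) > 2 && !is.na(sm$fstatistic[1])) {
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    } else NA_real_
    list(row = tibble::tibble(
      stratum = stratum,
      slope = unname(stats::coef(m)[2]),
      intercept = unname(stats::coef(m)[1]),
      pearson_r = stats::cor(df$x, df$y),
      adj_r2 = sm$adj.r.squared,
      p_value = unname(pv),
      n_genes = nrow(df)), model = m)
  }
  fits <- paired |>
    dplyr::group_by(.data$region) |>
    dplyr::group_map(~ fit_one(.x, .y$region))
  if (!is.null(filter_q)) {
    keep <- paired[!is.na(paired$q_x) & !is.na(paired$q_y) &
                     (paired$q_x < filter_q | paired$q_y < filter_q), ]
    fits <- c(fits, list(fit_one(keep, sprintf("pooled_q<%g", filter_q))))
  }
  out <- dplyr::bind_rows(purrr::map(fits, "row"))
  models <- purrr::map(fits, "model")
  names(models) <- out$stratum
  attr(out, "models") <- models
  class(out) <- c("consistency_fit", class(out))
  out
}

#' @export
print.consistency_fit <- function(x, ...) {
  cat("<consistency_fit> log2FC agreement between comparisons\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Broom-style tidiers for fold-change consistency fits
#'
#' `tidy()` returns per-stratum coefficient estimates with standard
#' errors; `glance()` returns the per-stratum fit summaries.
#'
#' @param x A `consistency_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy consistency_fit
#' @export
tidy.consistency_fit <- function(x, ...) {
  models <- attr(x, "models")
  purrr::imap(models, function(m, stratum) {
    if (is.null(m)) return(NULL)
    co <- summary(m)$coefficients
    tibble::tibble(stratum = stratum,
                   term = c("intercept", "slope"),
                   estimate = co[, 1], std_error = co[, 2],
                   statistic = co[, 3], p_value = co[, 4])
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.consistency_fit
#' @method glance consistency_fit
#' @export
glance.consistency_fit <- function(x, ...) {
  out <- x
  attr(out, "models") <- NULL
  class(out) <- setdiff(class(out), "consistency_fit")
  tibble::as_tibble(out)
}

#' Z-scored percent expression of restored genes across groups
#'
#' For each restored gene in a stratum, the percent expression in the
#' C-NB, C-NBF, and T-NBF groups, z-scored across the groups (by row) or
#' across genes within group (`margin = "column"`), for heatmap display.
#' Zero-variance rows become all-zero and are flagged.
#'
#' @param calls Output of [call_restored()].
#' @param pct Percent-expression tibble from [percent_expression()] with
#'   `cell_type`, `region`, `group`, `gene`, `pct`.
#' @param groups Groups to include, in display order.
#' @param margin `"row"` (z across groups, default) or `"column"`.
#' @return Tibble: `cell_type`, `region`, `gene`, `group`, `pct`, `z`,
#'   `zero_variance`.
#' @export
restored_heatmap_data <- function(calls, pct,
                                  groups = c("C-NB", "C-NBF", "T-NBF"),
                                  margin = c("row", "column")) {
  margin <- match.arg(margin)
  hits <- calls[!is.na(calls$status) &
                  calls$status %in% c("restored", "fully_restored"),
                c("gene", "cell_type", "region")]
  if (!nrow(hits)) stop("no restored genes to display")
  df <- dplyr::inner_join(hits, pct[pct$group %in% groups, ],
                          by = c("gene", "cell_type", "region"))
  zfun <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  grp_vars <- if (margin == "row") c("cell_type", "region", "gene") else
    c("cell_type", "region", "group")
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    dplyr::mutate(z = zfun(.data$pct),
                  zero_variance = stats::sd(.data$pct) == 0 |
                    is.na(stats::sd(.data$pct))) |>
    dplyr::ungroup() |>
    dplyr::select("cell_type", "region", "gene", "group", "pct", "z",
                  "zero_variance")
}
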