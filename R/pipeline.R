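#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end run: synthesize (or accept) a cohort,
#' ingest spots into a region-assigned cell matrix, classify cell types,
#' run pairwise percent-expression DEG over the configured comparisons,
#' call restored genes and fold-change consistency, compute densities with
#' group tests and Ripley curves in the EC, and bin + summarize expression.
#' All stage outputs are written as plain-text tables under `out_dir` with
#' MD5 checksums in the returned manifest; a rerun with the same
#' configuration and seed is bit-identical for the deterministic stages.
#'
#' @param config A [generator_config()] (used when `cohort` is NULL).
#' @param cohort Optional pre-built cohort (list with `spots`, `masks`,
#'   `metadata`), e.g. read from disk; ground truth is not required.
#' @param out_dir Output directory; `NULL` skips writing files.
#' @param cell_types Cell types for the DEG stage.
#' @param regions Regions for the DEG stage.
#' @param pairs Pairwise group comparisons.
#' @param alpha Significance threshold for restoration calls.
#' @param filter_q q filter for the pooled consistency fit.
#' @param fdr_scope See [deg_pairwise()].
#' @param bin_size Bin size (um) for the binned summary.
#' @param with_embedding Compute the UMAP embedding stage (slowest stage;
#'   the manifest records it either way).
#' @return List of stage results plus `manifest` (tibble of written files
#'   and checksums) and `params`.
#' @export
run_pipeline <- function(config = generator_config(), cohort = NULL,
                         out_dir = NULL,
                         cell_types = "neuron",
                         regions = c("CA1", "CA2", "CA3", "DG", "EC"),
                         pairs = default_comparisons(),
                         alpha = 0.05, filter_q = 0.2,
                         fdr_scope = "stratum",
                         bin_size = 50, with_embedding = FALSE) {
  stages <- list()
  if (is.null(cohort)) {
    cohort <- generate_cohort(config)
  }
  stages$synthesize <- cohort$metadata

  cm <- ingest_cohort(cohort)
  stages$ingest <- tibble::tibble(n_genes = nrow(cm$counts),
                                  n_cells = ncol(cm$counts))

  cm <- classify_cells(cm)
  stages$classify <- type_composition(cm)

  deg <- deg_pairwise(cm, cell_types = cell_types, regions = regions,
                      pairs = pairs, fdr_scope = fdr_scope)
  stages$deg <- deg

  cmp_lab <- purrr::map_chr(pairs, paste, collapse = "/")
  deg_cnb <- deg[deg$comparison == "C-NB/C-NBF", ]
  deg_tnbf <- deg[deg$comparison == "T-NBF/C-NBF", ]
  if (nrow(deg_cnb) && nrow(deg_tnbf)) {
    calls <- call_restored(deg_cnb, deg_tnbf, alpha = alpha)
    stages$restore <- calls
    stages$restore_summary <- restored_summary(calls)
    stages$consistency <- fc_consistency(deg_cnb, deg_tnbf,
                                         filter_q = filter_q)
  }

  dens <- cell_density(cm, cohort$masks)
  stages$density <- dens
  dg <- dens[dens$region == "DG", ]
  if (nrow(dg) >= 4) stages$density_tests <- density_group_tests(dg)
  curves <- ripley_by_type(cm, cohort$masks, region = "EC")
  stages$ripley <- curves
  stages$ripley_group <- group_ripley(curves)

  all_spots <- dplyr::bind_rows(cohort$spots)
  grid <- bin_spots(all_spots, bin_size = bin_size)
  stages$summary <- summarize_expression(cm)
  if (with_embedding) {
    grid <- label_bins(grid, cm)
    stages$embedding <- normalize_and_embed(grid, seed = config$seed)
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv0 <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
      p
    }
    files <- c(
      write_tsv0(cm$cells, "cells.tsv"),
      write_tsv0(deg, "deg.tsv"),
      if (!is.null(stages$restore)) write_tsv0(stages$restore, "restored.tsv"),
      write_tsv0(dens, "density.tsv"),
      write_tsv0(curves, "ripley.tsv"),
      write_tsv0(stages$summary$gene_totals, "gene_totals.tsv"),
      if (!is.null(stages$embedding)) write_tsv0(stages$embedding,
                                                 "embedding.tsv")
    )
    manifest <- tibble::tibble(file = basename(files),
                               md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(
      list(seed = config$seed, alpha = alpha, filter_q = filter_q,
           bin_size = bin_size, fdr_scope = fdr_scope,
           files = manifest),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  stages$manifest <- manifest
  stages$params <- list(seed = config$seed, alpha = alpha,
                        filter_q = filter_q, bin_size = bin_size,
                        fdr_scope = fdr_scope)
  stages
}
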