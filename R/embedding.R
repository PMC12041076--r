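#' Panel-wide expression summaries
#'
#' Per-cell unique-gene counts and their median, total spot counts per
#' gene, per-region top expressed genes, and the per-region percent
#' expression of the union of those top genes z-scored across regions
#' (column z-score) — the standard QC snapshot of a targeted-panel run.
#'
#' @param cells A `cell_matrix` (regions assigned for the per-region
#'   pieces; cells with region "none" are ignored there).
#' @param top_n Number of top genes per region (default 10).
#' @param min_spots_positive Positivity threshold for percent expression.
#' @return List: `unique_genes` (tibble cell_id, n_unique),
#'   `median_unique`, `gene_totals` (tibble, ranked), `top_by_region`,
#'   `region_pct_z` (tibble gene, region, pct, z).
#' @export
summarize_expression <- function(cells, top_n = 10,
                                 min_spots_positive = 1) {
  stopifnot(ncol(cells$counts) > 0)
  pos <- positivity_matrix(cells, min_spots_positive)
  n_unique <- Matrix::colSums(pos)
  unique_genes <- tibble::tibble(cell_id = cells$cells$cell_id,
                                 n_unique = as.integer(n_unique))
  gene_totals <- tibble::tibble(
    gene = rownames(cells$counts),
    total_spots = as.integer(Matrix::rowSums(cells$counts))
  ) |> dplyr::arrange(dplyr::desc(.data$total_spots))

  meta <- cells$cells
  has_region <- !is.na(meta$region) & meta$region != "none"
  top_by_region <- NULL
  region_pct_z <- NULL
  if (any(has_region)) {
    per_region <- purrr::map(unique(meta$region[has_region]), function(reg) {
      sel <- which(has_region & meta$region == reg)
      tibble::tibble(region = reg, gene = rownames(cells$counts),
                     total_spots = as.integer(
                       Matrix::rowSums(cells$counts[, sel, drop = FALSE])),
                     pct = 100 * Matrix::rowSums(pos[, sel, drop = FALSE]) /
                       length(sel))
    }) |> dplyr::bind_rows()
    top_by_region <- per_region |>
      dplyr::group_by(.data$region) |>
      dplyr::slice_max(.data$total_spots, n = top_n, with_ties = FALSE) |>
      dplyr::ungroup()
    union_genes <- unique(top_by_region$gene)
    region_pct_z <- per_region |>
      dplyr::filter(.data$gene %in% union_genes) |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(z = {
        s <- stats::sd(.data$pct)
        if (is.na(s) || s == 0) rep(0, dplyr::n())
        else (.data$pct - mean(.data$pct)) / s
      }) |>
      dplyr::ungroup() |>
      dplyr::select("gene", "region", "pct", "z")
  }
  list(unique_genes = unique_genes,
       median_unique = stats::median(unique_genes$n_unique),
       gene_totals = gene_totals,
       top_by_region = top_by_region,
       region_pct_z = region_pct_z)
}

#' Bin spots on a square grid
#'
#' Divides the bounding rectangle of the contour into `bin_size` x
#' `bin_size` squares (50 um by default) and counts spots of each gene per
#' bin. Spots outside the contour polygon are excluded; included spot
#' totals are conserved by construction.
#'
#' @param spots Spot tibble (all samples pooled or one sample).
#' @param contour Polygon bounding the tissue of interest; `NULL` uses the
#'   bounding box of the spots.
#' @param bin_size Bin side length in micrometres (> 0).
#' @return Object of class `bin_grid`: list with `counts` (bins x genes
#'   sparse matrix), `bins` tibble (`bin_id`, `x_center`, `y_center`,
#'   per-bin majority `sample_id`), `bin_size`.
#' @export
bin_spots <- function(spots, contour = NULL, bin_size = 50) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (!is.null(contour)) {
    keep <- point_in_polygon(spots$x, spots$y, contour)
    spots <- spots[keep, , drop = FALSE]
  }
  if (!nrow(spots)) stop("no spots inside the contour")
  x0 <- min(spots$x); y0 <- min(spots$y)
  ix <- floor((spots$x - x0) / bin_size)
  iy <- floor((spots$y - y0) / bin_size)
  bin_key <- paste0(ix, "_", iy)
  bins <- sort(unique(bin_key))
  genes <- sort(unique(spots$gene))
  counts <- Matrix::sparseMatrix(
    i = match(bin_key, bins), j = match(spots$gene, genes), x = 1,
    dims = c(length(bins), length(genes)),
    dimnames = list(bins, genes))
  ij <- do.call(rbind, strsplit(bins, "_", fixed = TRUE))
  maj <- function(v) names(sort(table(v), decreasing = TRUE))[1]
  sample_of <- tapply(spots$sample_id, bin_key, maj)[bins]
  bins_tbl <- tibble::tibble(
    bin_id = bins,
    x_center = x0 + (as.numeric(ij[, 1]) + 0.5) * bin_size,
    y_center = y0 + (as.numeric(ij[, 2]) + 0.5) * bin_size,
    sample_id = unname(sample_of)
  )
  structure(list(counts = counts, bins = bins_tbl, bin_size = bin_size),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", nrow(x$counts), " bins x ", ncol(x$counts),
      " genes, bin size ", x$bin_size, " um\n", sep = "")
  invisible(x)
}

#' Label bins by the majority region/group of contained cells
#'
#' @param grid A `bin_grid`.
#' @param cells A `cell_matrix` with regions (and groups) assigned.
#' @return The grid with `region` and `group` columns added to `$bins`.
#' @export
label_bins <- function(grid, cells) {
  meta <- cells$cells
  x0 <- grid$bins$x_center - grid$bin_size / 2
  ix <- floor((meta$x - min(x0)) / grid$bin_size)
  y0 <- grid$bins$y_center - grid$bin_size / 2
  iy <- floor((meta$y - min(y0)) / grid$bin_size)
  key <- paste0(ix, "_", iy)
  maj <- function(v) {
    v <- v[!is.na(v) & v != "none"]
    if (!length(v)) return(NA_character_)
    names(sort(table(v), decreasing = TRUE))[1]
  }
  grid$bins$region <- unname(tapply(meta$region, key, maj)[grid$bins$bin_id])
  grid$bins$group <- unname(tapply(meta$group, key, maj)[grid$bins$bin_id])
  grid
}

#' Median-normalize, log-transform, and embed binned counts
#'
#' Scales every nonempty bin to the median bin total, applies ln(1 + x),
#' and computes a 2-D embedding (UMAP by default, PCA as a deterministic
#' alternative). The normalization preserves the zero pattern; post-scaling
#' bin totals all equal the median.
#'
#' @param grid A `bin_grid`.
#' @param seed Seed for the embedding.
#' @param method `"umap"` or `"pca"`.
#' @param min_bins Minimum number of nonempty bins required.
#' @param n_neighbors UMAP neighborhood size.
#' @return Tibble: bin metadata plus embedding coordinates `e1`, `e2`;
#'   the normalized matrix is in the `"normalized"` attribute.
#' @export
normalize_and_embed <- function(grid, seed = 1L,
                                method = c("umap", "pca"),
                                min_bins = 10, n_neighbors = 15) {
  method <- match.arg(method)
  totals <- Matrix::rowSums(grid$counts)
  keep <- totals > 0
  if (sum(keep) < min_bins) stop("fewer than ", min_bins, " nonempty bins")
  m <- grid$counts[keep, , drop = FALSE]
  med <- stats::median(totals[keep])
  norm <- Matrix::Diagonal(x = med / totals[keep]) %*% m
  lx <- log1p(as.matrix(norm))
  emb <- if (method == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("method = 'umap' needs the uwot package")
    }
    set.seed(seed)
    uwot::umap(lx, n_neighbors = min(n_neighbors, sum(keep) - 1),
               n_threads = 1, seed = seed)
  } else {
    stats::prcomp(lx, center = TRUE, scale. = FALSE)$x[, 1:2]
  }
  out <- grid$bins[keep, , drop = FALSE]
  out$e1 <- emb[, 1]
  out$e2 <- emb[, 2]
  attr(out, "normalized") <- lx
  out
}
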