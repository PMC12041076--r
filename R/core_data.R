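#' Read a decoded-spot table
#'
#' Reads the per-spot CSV produced by in situ sequencing decoding (one row
#' per decoded rolling-circle product: gene label plus image coordinates,
#' with an upstream cell assignment). Spots whose gene label is not on the
#' panel are dropped and the drop count reported via a message and the
#' `"dropped_off_panel"` attribute.
#'
#' @param path CSV file path.
#' @param panel Character vector of panel gene symbols.
#' @param columns Named character vector mapping the canonical names
#'   `gene`, `x`, `y`, `cell_id` (and optionally `sample_id`) to the file's
#'   column names.
#' @param sample_id Sample identifier to stamp on every row when the file
#'   has no sample column.
#' @return Tibble with columns `gene`, `x`, `y`, `cell_id`, `sample_id`.
#' @export
read_spots <- function(path, panel = gene_panel(),
                       columns = c(gene = "gene", x = "x", y = "y",
                                   cell_id = "cell_id"),
                       sample_id = NULL) {
  if (!file.exists(path)) stop("spot file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) stop("spot file is empty: ", path)
  need <- c("gene", "x", "y", "cell_id")
  for (nm in need) {
    if (is.na(columns[nm]) || !(columns[nm] %in% names(raw))) {
      stop("spot file missing required column '", columns[nm] %||% nm,
           "' (mapped from '", nm, "')")
    }
  }
  out <- tibble::tibble(
    gene = as.character(raw[[columns["gene"]]]),
    x = as.numeric(raw[[columns["x"]]]),
    y = as.numeric(raw[[columns["y"]]]),
    cell_id = raw[[columns["cell_id"]]]
  )
  if ("sample_id" %in% names(columns) && columns["sample_id"] %in% names(raw)) {
    out$sample_id <- as.character(raw[[columns["sample_id"]]])
  } else {
    out$sample_id <- sample_id %||% tools::file_path_sans_ext(basename(path))
  }
  if (!all(is.finite(out$x)) || !all(is.finite(out$y))) {
    stop("non-finite spot coordinates in ", path)
  }
  keep <- out$gene %in% panel
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " spot(s) with off-panel gene labels dropped")
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "dropped_off_panel") <- dropped
  out
}

#' Write a spot table to CSV
#'
#' @param spots Spot tibble (`gene`, `x`, `y`, `cell_id`, `sample_id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spots <- function(spots, path) {
  utils::write.csv(spots[, c("gene", "x", "y", "cell_id", "sample_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a cell matrix from a counts matrix and per-cell metadata
#'
#' Low-level constructor for users who already hold a gene x cell count
#' matrix (e.g. from upstream segmentation output) rather than a spot
#' table. Metadata columns missing from `cells` are filled with NA.
#'
#' @param counts Nonnegative integer matrix, genes x cells, with
#'   dimnames.
#' @param cells Data frame with one row per column of `counts`; must
#'   contain `cell_id` matching the column names, and may contain `x`,
#'   `y`, `sample_id`, `subject_id`, `group`, `hemisphere`, `region`,
#'   `in_sgl`, `cell_type`.
#' @return A `cell_matrix`.
#' @export
cell_matrix <- function(counts, cells) {
  cells <- tibble::as_tibble(cells)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            "cell_id" %in% names(cells))
  cells$cell_id <- as.character(cells$cell_id)
  stopifnot(identical(colnames(counts), cells$cell_id))
  if (any(counts < 0)) stop("counts must be nonnegative")
  defaults <- list(x = NA_real_, y = NA_real_, sample_id = NA_character_,
                   subject_id = NA_character_, group = NA_character_,
                   hemisphere = NA_character_, region = NA_character_,
                   in_sgl = NA, cell_type = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(cells)) cells[[nm]] <- defaults[[nm]]
  }
  new_cell_matrix(counts, cells)
}

new_cell_matrix <- function(counts, cells, unassigned_spots = 0L) {
  stopifnot(inherits(counts, "Matrix") || is.matrix(counts))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  stopifnot(ncol(counts) == nrow(cells))
  stopifnot(identical(colnames(counts), cells$cell_id))
  structure(list(counts = counts, cells = tibble::as_tibble(cells),
                 unassigned_spots = as.integer(unassigned_spots)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("<cell_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  cat("  samples: ", paste(unique(x$cells$sample_id), collapse = ", "), "\n",
      sep = "")
  if (!all(is.na(x$cells$region))) {
    cat("  regions assigned: ",
        paste(sort(unique(x$cells$region)), collapse = ", "), "\n", sep = "")
  }
  if (!all(is.na(x$cells$cell_type))) {
    cat("  cell types assigned\n")
  }
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Per-cell metadata of a cell matrix as a tibble
#'
#' @param x A `cell_matrix`.
#' @param ... Unused.
#' @return The per-cell metadata tibble (`cell_id`, centroid `x`/`y`,
#'   `sample_id`, `subject_id`, `hemisphere`, `group`, `region`, `in_sgl`,
#'   `cell_type`).
#' @method as_tibble cell_matrix
#' @export
as_tibble.cell_matrix <- function(x, ...) x$cells

#' @rdname as_tibble.cell_matrix
#' @method tidy cell_matrix
#' @export
tidy.cell_matrix <- function(x, ...) x$cells

#' Build a gene-by-cell count matrix from assigned spots
#'
#' Tabulates spots into the gene x cell count matrix (entry = number of
#' spots of that gene assigned to that cell) and computes each cell's
#' centroid as the mean of its spot coordinates. Spots with a missing cell
#' assignment are excluded and counted in the `unassigned_spots` field.
#'
#' @param spots Spot tibble for one sample (see [read_spots()]).
#' @param meta One-row tibble with `sample_id`, `subject_id`, `group`,
#'   `hemisphere` for this sample.
#' @param panel Gene panel ordering the matrix rows.
#' @return A `cell_matrix`.
#' @export
build_cell_matrix <- function(spots, meta, panel = gene_panel()) {
  stopifnot(nrow(meta) == 1)
  unassigned <- is.na(spots$cell_id)
  n_unassigned <- sum(unassigned)
  spots <- spots[!unassigned, , drop = FALSE]
  if (nrow(spots) == 0) stop("no spots carry a cell assignment")
  off <- setdiff(unique(spots$gene), panel)
  if (length(off)) stop("spots contain off-panel genes: ",
                        paste(off, collapse = ", "))
  cell_ids <- sort(unique(spots$cell_id))
  gi <- match(spots$gene, panel)
  ci <- match(spots$cell_id, cell_ids)
  counts <- Matrix::sparseMatrix(i = gi, j = ci, x = 1,
                                 dims = c(length(panel), length(cell_ids)),
                                 dimnames = list(panel, as.character(cell_ids)))
  cent <- spots |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    dplyr::arrange(match(.data$cell_id, cell_ids))
  cells <- tibble::tibble(
    cell_id = as.character(cell_ids),
    x = cent$x, y = cent$y,
    sample_id = meta$sample_id,
    subject_id = meta$subject_id %||% NA_character_,
    group = as.character(meta$group %||% NA_character_),
    hemisphere = meta$hemisphere %||% NA_character_,
    region = NA_character_, in_sgl = FALSE, cell_type = NA_character_
  )
  new_cell_matrix(counts, cells, unassigned_spots = n_unassigned)
}

#' Assign cells to annotated regions
#'
#' Labels each cell with the region whose polygon contains its centroid
#' (boundary counts as inside). Cells inside no polygon get region
#' `"none"`. The subgranular layer (SGL) is nested within the DG: SGL
#' membership is recorded as the logical flag `in_sgl` in addition to
#' `region = "DG"`. When a centroid falls inside several non-SGL polygons
#' the smallest-area polygon wins (deterministic nesting tie-break) and a
#' warning is raised.
#'
#' @param cells A `cell_matrix`.
#' @param masks Mask-set tibble (see [region_masks()]).
#' @param convex_hull Assign by convex hull of each polygon instead of the
#'   polygon itself (reproduces hull-based assignment; off by default
#'   because the regions are non-convex).
#' @return The `cell_matrix` with `region` and `in_sgl` filled in.
#' @export
assign_regions <- function(cells, masks, convex_hull = FALSE) {
  meta <- cells$cells
  region <- rep("none", nrow(meta))
  region_area <- rep(Inf, nrow(meta))
  in_sgl <- rep(FALSE, nrow(meta))
  multi <- rep(0L, nrow(meta))
  for (sid in unique(meta$sample_id)) {
    sel <- meta$sample_id == sid
    m <- masks[masks$sample_id == sid, , drop = FALSE]
    for (k in seq_len(nrow(m))) {
      inside <- point_in_polygon(meta$x[sel], meta$y[sel], m$vertices[[k]],
                                 convex_hull = convex_hull)
      if (m$region[k] == "SGL") {
        in_sgl[sel][inside] <- TRUE
      } else {
        idx <- which(sel)[inside]
        multi[idx] <- multi[idx] + 1L
        take <- m$area_mm2[k] < region_area[idx]
        region[idx[take]] <- m$region[k]
        region_area[idx[take]] <- m$area_mm2[k]
      }
    }
  }
  if (any(multi > 1L)) {
    warning(sum(multi > 1L), " cell(s) inside multiple non-SGL polygons; ",
            "smallest-area polygon kept")
  }
  cells$cells$region <- region
  cells$cells$in_sgl <- in_sgl
  cells
}

#' Concatenate per-sample cell matrices
#'
#' Column-binds matrices over an identical gene panel; cell ids are
#' disambiguated with a `sample_id:` prefix.
#'
#' @param matrices List of `cell_matrix` objects.
#' @return A single `cell_matrix`.
#' @export
concat_samples <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  panel <- rownames(matrices[[1]]$counts)
  for (m in matrices) {
    if (!identical(rownames(m$counts), panel)) {
      stop("cell matrices have mismatched gene panels")
    }
  }
  parts <- purrr::map(matrices, function(m) {
    cm <- m$counts
    cells <- m$cells
    new_ids <- paste0(cells$sample_id, ":", cells$cell_id)
    colnames(cm) <- new_ids
    cells$cell_id <- new_ids
    list(counts = cm, cells = cells)
  })
  counts <- do.call(cbind, purrr::map(parts, "counts"))
  cells <- dplyr::bind_rows(purrr::map(parts, "cells"))
  new_cell_matrix(counts, cells,
                  unassigned_spots = sum(purrr::map_int(matrices,
                                                        "unassigned_spots")))
}

#' Export a cell matrix as MTX plus TSV sidecars
#'
#' @param cells A `cell_matrix`.
#' @param dir Output directory (created if needed). Writes `counts.mtx`,
#'   `genes.tsv`, `cells.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cells$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "genes.tsv"))
  utils::write.table(cells$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
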