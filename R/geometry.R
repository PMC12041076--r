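#' Point-in-polygon test
#'
#' Even-odd containment with boundary points counted as inside. This is the
#' primitive behind region assignment; it is deliberately exact polygon
#' containment rather than convex-hull containment, because hippocampal
#' region masks (DG blades, CA bands) are non-convex. Convex-hull behaviour
#' is available via `convex_hull = TRUE`.
#'
#' @param x,y Numeric vectors of point coordinates.
#' @param vertices Two-column matrix (or data frame) of polygon vertices.
#' @param convex_hull If TRUE, test against the convex hull of the vertices
#'   instead of the polygon itself.
#' @return Logical vector: TRUE when the point is inside or on the boundary.
#' @export
point_in_polygon <- function(x, y, vertices, convex_hull = FALSE) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  if (convex_hull) {
    vertices <- vertices[grDevices::chull(vertices[, 1], vertices[, 2]), , drop = FALSE]
  }
  # sp codes: 0 outside, 1 inside, 2 on an edge, 3 on a vertex
  code <- sp::point.in.polygon(x, y, vertices[, 1], vertices[, 2])
  code > 0
}

#' Polygon area by the shoelace formula
#'
#' @param vertices Two-column matrix of (x, y) vertices in order.
#' @return Unsigned area in squared input units.
#' @export
polygon_area <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  x <- vertices[, 1]; y <- vertices[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_is_simple <- function(vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  if (n < 3) return(FALSE)
  seg <- cbind(v, rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]))
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip segments sharing an endpoint
    for (j in js) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Build a region mask set
#'
#' A mask set is a tibble with one row per (sample, region) polygon: the
#' vertex list in micrometres and the enclosed area in mm^2 (shoelace
#' formula, scaled by `um_per_unit`).
#'
#' @param polygons Named list: `polygons[[sample_id]][[region]]` is a
#'   two-column vertex matrix.
#' @param um_per_unit Micrometres per coordinate unit (1 when coordinates
#'   are already in micrometres).
#' @return Tibble with columns `sample_id`, `region`, `vertices`
#'   (list-column of matrices), `area_mm2`.
#' @export
region_masks <- function(polygons, um_per_unit = 1) {
  rows <- purrr::imap(polygons, function(regs, sid) {
    purrr::imap(regs, function(v, reg) {
      v <- as.matrix(v)
      if (!polygon_is_simple(v)) {
        stop("polygon for ", sid, "/", reg, " is self-intersecting")
      }
      area <- polygon_area(v * um_per_unit) / 1e6
      if (area <= 0) stop("polygon for ", sid, "/", reg, " has zero area")
      tibble::tibble(sample_id = sid, region = reg,
                     vertices = list(v * um_per_unit), area_mm2 = area)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("region_mask_set", class(out))
  out
}

#' Read region masks from JSON
#'
#' Expected layout: `{sample: {region: [[x, y], ...], ...}, ...}`.
#'
#' @param path JSON file path.
#' @inheritParams region_masks
#' @return A mask-set tibble, see [region_masks()].
#' @export
read_masks <- function(path, um_per_unit = 1) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- purrr::map(raw, function(regs) purrr::map(regs, as.matrix))
  region_masks(polys, um_per_unit = um_per_unit)
}

#' Write region masks to JSON
#'
#' @param masks Mask-set tibble from [region_masks()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  out <- split(masks, masks$sample_id)
  out <- purrr::map(out, function(df) {
    stats::setNames(purrr::map(df$vertices, ~ unname(as.matrix(.x))), df$region)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
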