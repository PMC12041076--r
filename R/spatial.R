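#' Ripley's K and L functions for one point set
#'
#' Computes the uncorrected estimator
#' `K(t) = (1/lambda) * sum_i sum_{j != i} I(d_ij < t) / n` with
#' `lambda = n / A`, and its variance-stabilized form `L(t) =
#' sqrt(K(t) / pi)` (under complete spatial randomness `L(t) ~ t`).
#' No edge correction is applied by default — the estimator is used as
#' defined; an isotropic Ripley correction is available via
#' `edge_correction` for sensitivity checks (it requires a rectangular
#' window and is not used by the acceptance analyses).
#'
#' @param points Two-column matrix (or data frame) of coordinates in
#'   micrometres.
#' @param area Region area in the same squared units.
#' @param t_grid Increasing positive radii.
#' @param sample_id,cell_type Optional labels carried into the result.
#' @param edge_correction `"none"` (default) or `"ripley-isotropic"`.
#' @return Tibble with `t`, `K`, `L` (plus labels); all-NA with the
#'   `"degenerate"` attribute set when fewer than 2 points.
#' @export
ripley_K <- function(points, area, t_grid, sample_id = NA_character_,
                     cell_type = NA_character_,
                     edge_correction = c("none", "ripley-isotropic")) {
  edge_correction <- match.arg(edge_correction)
  points <- as.matrix(points)
  stopifnot(area > 0, all(diff(t_grid) > 0), all(t_grid > 0))
  n <- nrow(points)
  out <- tibble::tibble(sample_id = sample_id, cell_type = cell_type,
                        t = t_grid, K = NA_real_, L = NA_real_, n = n)
  if (n < 2) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (edge_correction == "none") {
    ds <- sort(stats::dist(points))
    # ordered pairs with d_ij < t (strict), each unordered pair counted twice
    n_lt <- 2 * findInterval(t_grid, ds, left.open = TRUE)
    K <- (area / n) * n_lt / n
  } else {
    if (!requireNamespace("spatstat.explore", quietly = TRUE)) {
      stop("edge_correction = 'ripley-isotropic' needs spatstat.explore")
    }
    bb <- apply(points, 2, range)
    win <- spatstat.geom::owin(xrange = bb[, 1], yrange = bb[, 2])
    pp <- spatstat.geom::ppp(points[, 1], points[, 2], window = win)
    kest <- spatstat.explore::Kest(pp, r = c(0, t_grid), correction = "iso")
    K <- kest$iso[-1]
  }
  out$K <- K
  out$L <- sqrt(K / pi)
  out
}

#' Ripley curves for every (cell type, sample) in a region
#'
#' @param cells A classified `cell_matrix`.
#' @param masks Mask-set tibble (for region areas).
#' @param region Region to analyze (EC by default).
#' @param t_grid Radii; default 50 points from 0 (exclusive) to half the
#'   region bounding-box diagonal of the first sample.
#' @param cell_types Cell types to include.
#' @return Tibble of curves with `group` attached from the metadata.
#' @export
ripley_by_type <- function(cells, masks, region = "EC", t_grid = NULL,
                           cell_types = cell_type_levels()) {
  meta <- cells$cells
  m <- masks[masks$region == region, , drop = FALSE]
  if (is.null(t_grid)) {
    v <- m$vertices[[1]]
    diag_len <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
    t_grid <- seq(0, diag_len / 2, length.out = 51)[-1]
  }
  combos <- tidyr::expand_grid(sample_id = unique(m$sample_id),
                               cell_type = cell_types)
  out <- purrr::pmap(combos, function(sample_id, cell_type) {
    sel <- meta$sample_id == sample_id & meta$region == region &
      meta$cell_type == cell_type
    area_um2 <- m$area_mm2[m$sample_id == sample_id][1] * 1e6
    cv <- ripley_K(cbind(meta$x[sel], meta$y[sel]), area_um2, t_grid,
                   sample_id = sample_id, cell_type = cell_type)
    cv$group <- meta$group[match(sample_id, meta$sample_id)]
    cv
  })
  dplyr::bind_rows(out)
}

#' Group mean and SEM of Ripley L curves
#'
#' @param curves Curve tibble from [ripley_by_type()] (needs `group`,
#'   `cell_type`, `sample_id`, `t`, `L`).
#' @return Tibble per (cell_type, group, t): `mean_L`, `sem_L` (`NA` SEM
#'   for a single sample), `n_samples`.
#' @export
group_ripley <- function(curves) {
  curves |>
    dplyr::filter(!is.na(.data$L)) |>
    dplyr::group_by(.data$cell_type, .data$group, .data$t) |>
    dplyr::summarise(
      mean_L = mean(.data$L),
      sem_L = if (dplyr::n() > 1) stats::sd(.data$L) / sqrt(dplyr::n()) else NA_real_,
      n_samples = dplyr::n(), .groups = "drop") |>
    structure(class = c("grouped_ripley", class(tibble::tibble())))
}

#' Monte-Carlo envelope for complete spatial randomness
#'
#' Simulates `nsim` uniform (binomial, fixed n) patterns in the polygon
#' and returns envelopes of L(t) under the same uncorrected estimator, so
#' observed curves are compared like-with-like. `type = "global"`
#' (default) builds a simultaneous envelope from the distribution of the
#' maximum absolute deviation around the simulated mean curve — an
#' entire CSR curve stays inside it with probability `level`, which is
#' the property "the curve lies within the envelope" actually needs;
#' `"pointwise"` gives per-radius quantiles (narrower, but a full CSR
#' curve escapes a 95% pointwise band far more often than 5% of the
#' time).
#'
#' @param n Number of points per simulation.
#' @param vertices Region polygon.
#' @param t_grid Radii.
#' @param nsim Number of simulations (default 199).
#' @param level Coverage (default 0.95).
#' @param type `"global"` or `"pointwise"`.
#' @return Tibble with `t`, `lo`, `hi`, `mean_L`.
#' @export
csr_envelope <- function(n, vertices, t_grid, nsim = 199, level = 0.95,
                         type = c("global", "pointwise")) {
  type <- match.arg(type)
  area <- polygon_area(vertices)
  sims <- vapply(seq_len(nsim), function(i) {
    pts <- sample_in_polygon(n, vertices)
    ripley_K(pts, area, t_grid)$L
  }, numeric(length(t_grid)))
  mean_L <- rowMeans(sims)
  if (type == "pointwise") {
    a <- (1 - level) / 2
    lo <- apply(sims, 1, stats::quantile, probs = a)
    hi <- apply(sims, 1, stats::quantile, probs = 1 - a)
  } else {
    d_max <- apply(abs(sims - mean_L), 2, max)
    w <- stats::quantile(d_max, probs = level)
    lo <- mean_L - w
    hi <- mean_L + w
  }
  tibble::tibble(t = t_grid, lo = unname(lo), hi = unname(hi),
                 mean_L = mean_L)
}

#' Cell densities per region (and optionally cell type)
#'
#' @param cells A `cell_matrix` with regions assigned.
#' @param masks Mask-set tibble with areas in mm^2.
#' @param by_type Also stratify by cell type.
#' @return Tibble: `sample_id`, `region` (, `cell_type`), `n_cells`,
#'   `area_mm2`, `density` (cells/mm^2), plus `group`.
#' @export
cell_density <- function(cells, masks, by_type = FALSE) {
  meta <- cells$cells
  if (any(masks$area_mm2 <= 0)) stop("zero-area region mask")
  vars <- c("sample_id", "region", if (by_type) "cell_type")
  counts <- meta[meta$region != "none", ] |>
    dplyr::count(dplyr::across(dplyr::all_of(vars)), name = "n_cells")
  out <- dplyr::inner_join(counts,
                           masks[, c("sample_id", "region", "area_mm2")],
                           by = c("sample_id", "region")) |>
    dplyr::mutate(density = .data$n_cells / .data$area_mm2)
  out$group <- meta$group[match(out$sample_id, meta$sample_id)]
  out
}

#' Group comparisons of per-sample densities
#'
#' One-way ANOVA and the Kruskal-Wallis rank-sum test of a per-sample
#' value across groups (df = groups - 1).
#'
#' @param density_tbl Tibble with one row per sample.
#' @param value Column name of the value to compare (default "density").
#' @param group Column name of the grouping factor.
#' @return One-row tibble: `anova_F`, `anova_p`, `kw_chisq`, `kw_df`,
#'   `kw_p`, `n`. ANOVA statistics are NA (flagged) when the residual
#'   variance is zero.
#' @export
density_group_tests <- function(density_tbl, value = "density",
                                group = "group") {
  v <- density_tbl[[value]]
  g <- factor(density_tbl[[group]])
  stopifnot(nlevels(g) >= 2)
  if (stats::sd(v) == 0) {
    # all-identical values: no evidence of any group difference
    return(tibble::tibble(anova_F = NA_real_, anova_p = NA_real_,
                          kw_chisq = 0, kw_df = nlevels(g) - 1, kw_p = 1,
                          n = length(v)))
  }
  kw <- stats::kruskal.test(v, g)
  aov_F <- aov_p <- NA_real_
  fit <- stats::aov(v ~ g)
  sm <- summary(fit)[[1]]
  if (nrow(sm) == 2 && sm["Residuals", "Mean Sq"] > 0) {
    aov_F <- sm[1, "F value"]
    aov_p <- sm[1, "Pr(>F)"]
  }
  tibble::tibble(anova_F = aov_F, anova_p = aov_p,
                 kw_chisq = unname(kw$statistic),
                 kw_df = unname(kw$parameter),
                 kw_p = kw$p.value, n = length(v))
}

#' Estimate entorhinal-cortex upper/lower layers from Calb1 coordinates
#'
#' The EC layer boundary is estimated per sample from Calb1 expression as
#' an upper-layer proxy. The depth axis is chosen from the two principal
#' axes of the EC cell centroids as the one along which the
#' marker-positive cells separate most from the overall population
#' (standardized distance between the marker median and the overall
#' median) — cortical layers run along the long axis of the EC strip, so
#' the depth direction is not reliably the major axis, but it is the axis
#' where an upper-layer marker is displaced. The axis is oriented so the
#' median marker projection lies on the negative (upper) side; the
#' boundary sits one standard deviation of the marker projections beyond
#' their median. Cells at depth <= boundary are "upper" (layers 1-3), the
#' rest "lower" (layers 4-6). The construction is translation- and
#' rotation-invariant.
#'
#' @param cells A classified `cell_matrix`.
#' @param sample_id Sample to process.
#' @param marker Upper-layer proxy gene (default Calb1).
#' @param min_marker_cells Minimum marker-positive EC cells required.
#' @param min_spots_positive Positivity threshold.
#' @return Tibble `cell_id`, `layer`, `depth` for the sample's EC cells;
#'   attributes `boundary`, `axis`, `center`.
#' @export
estimate_ec_layers <- function(cells, sample_id, marker = "Calb1",
                               min_marker_cells = 10,
                               min_spots_positive = 1) {
  meta <- cells$cells
  sel <- which(meta$sample_id == sample_id & meta$region == "EC")
  if (!length(sel)) stop("no EC cells in sample ", sample_id)
  xy <- cbind(meta$x[sel], meta$y[sel])
  pos <- positivity_matrix(cells, min_spots_positive)
  calb <- as.vector(pos[marker, sel])
  if (sum(calb) < min_marker_cells) {
    stop("fewer than ", min_marker_cells, " ", marker,
         "-positive EC cells in ", sample_id,
         "; provide manual layer masks instead")
  }
  pc <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  sep <- vapply(1:2, function(k) {
    proj <- pc$x[, k]
    abs(stats::median(proj[calb]) - stats::median(proj)) / stats::sd(proj)
  }, numeric(1))
  ax <- which.max(sep)
  depth <- pc$x[, ax]
  if (stats::median(depth[calb]) > stats::median(depth)) depth <- -depth
  boundary <- stats::median(depth[calb]) + stats::sd(depth[calb])
  out <- tibble::tibble(
    cell_id = meta$cell_id[sel],
    depth = depth,
    layer = ifelse(depth <= boundary, "upper", "lower")
  )
  attr(out, "boundary") <- boundary
  attr(out, "axis") <- pc$rotation[, ax]
  attr(out, "center") <- pc$center
  out
}
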