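#' Default region polygon templates
#'
#' Simple labeled geometry standing in for manually annotated hippocampal
#' region masks: bands for the CA fields, a block DG with a thin nested SGL
#' strip along its lower third, and a trapezoidal EC wedge. Coordinates are
#' micrometres in image convention (y increases downward). Realistic
#' anatomy is not attempted; only labeled, non-convex-capable polygon
#' geometry with plausible areas matters downstream.
#'
#' @return Named list of two-column vertex matrices (CA1, CA2, CA3, DG,
#'   SGL, EC). SGL lies inside DG.
#' @export
default_region_polygons <- function() {
  rect <- function(x0, x1, y0, y1) {
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  list(
    CA1 = rect(200, 2800, 200, 500),
    CA2 = rect(2200, 2800, 550, 800),
    CA3 = rect(200, 1400, 550, 900),
    DG  = rect(600, 1800, 1000, 1500),
    SGL = rect(600, 1800, 1350, 1500),
    EC  = cbind(x = c(200, 2800, 2600, 400), y = c(1800, 1800, 2600, 2600))
  )
}

#' Default per-cell-type detection-probability profiles
#'
#' Builds the cell-type x gene matrix of per-gene detection probabilities
#' pi used by the generator. Profiles are rule-conforming with respect to
#' [marker_rules()]: genes a type's classification path requires to be
#' absent get pi = 1e-4 (small enough that joint leakage across the
#' 37-gene inhibitory marker set stays well under 1%), required/defining
#' positives get high pi, and genes outside all rules get a common
#' background probability calibrated so that cells express a median of
#' about five unique genes.
#'
#' @param panel Gene panel.
#' @param rules Marker rule set.
#' @param background Detection probability for non-rule, non-marker genes.
#' @param negative Detection probability for required-negative rule genes.
#' @return Numeric matrix, rows = [cell_type_levels()], columns = panel.
#' @export
default_profiles <- function(panel = gene_panel(), rules = marker_rules(),
                             background = 0.008, negative = 1e-4) {
  types <- cell_type_levels()
  pi <- matrix(background, nrow = length(types), ncol = length(panel),
               dimnames = list(types, panel))
  set_pi <- function(type, genes, p) {
    genes <- intersect(genes, panel)
    pi[type, genes] <<- p
  }
  excl <- rules$neuron_exclusion
  imm_pos <- rules$immature_positive
  inh <- rules$inhibitory_markers

  # neurons: all exclusion genes must be absent
  for (t in c("immature", "excitatory", "inhibitory")) set_pi(t, excl, negative)

  # excitatory: no inhibitory marker, no immature trigger
  set_pi("excitatory", inh, negative)
  set_pi("excitatory", c(imm_pos, "Prox1"), negative)
  set_pi("excitatory", "Rbfox3", 0.90)
  set_pi("excitatory", "Syn1", 0.55)
  set_pi("excitatory", "Map2", 0.40)
  set_pi("excitatory", "Tubb3", 0.30)
  set_pi("excitatory", "Slc17a7", 0.65)
  set_pi("excitatory", "Camk2a", 0.55)
  set_pi("excitatory", "Nrgn", 0.45)
  set_pi("excitatory", "App", 0.45)
  set_pi("excitatory", "Tbr1", 0.35)
  set_pi("excitatory", "Slc17a8", 0.30)

  # inhibitory: pan-neuronal plus interneuron markers
  set_pi("inhibitory", c(imm_pos, "Prox1"), negative)
  set_pi("inhibitory", "Rbfox3", 0.90)
  set_pi("inhibitory", "Syn1", 0.55)
  set_pi("inhibitory", "Map2", 0.40)
  set_pi("inhibitory", "Gad1", 0.95)
  set_pi("inhibitory", "Gad2", 0.70)
  set_pi("inhibitory", "Slc6a1", 0.50)
  set_pi("inhibitory", "Pvalb", 0.30)
  set_pi("inhibitory", "Sst", 0.25)
  set_pi("inhibitory", "Npy", 0.20)
  set_pi("inhibitory", "Cck", 0.30)

  # immature: SGL-resident, Dcx/Neurod1/Ncam1 positive, Rbfox3 negative
  set_pi("immature", inh, background)
  set_pi("immature", "Dcx", 0.95)
  set_pi("immature", "Ncam1", 0.60)
  set_pi("immature", "Neurod1", 0.60)
  set_pi("immature", "Prox1", 0.90)
  set_pi("immature", "Rbfox3", negative)

  # astrocyte: Aldoc+ with Laptm5/Acta2/Kcnj8 absent
  set_pi("astrocyte", c(rules$astro_negative, "Mbp", "Plp1", "Itgam", "Dcn"),
         negative)
  set_pi("astrocyte", "Aldoc", 0.995)
  set_pi("astrocyte", "Aqp4", 0.80)
  set_pi("astrocyte", "Gfap", 0.60)
  set_pi("astrocyte", "Gja1", 0.50)
  set_pi("astrocyte", "S1pr1", 0.30)
  set_pi("astrocyte", "Glul", 0.60)
  set_pi("astrocyte", "Apoe", 0.50)

  # microglia: Laptm5+ with Aldoc/Acta2/Kcnj8 absent
  set_pi("microglia", c(rules$micro_negative, "Mbp", "Plp1", "Gfap", "Gja1",
                        "Aqp4", "S1pr1", "Dcn"), negative)
  set_pi("microglia", "Laptm5", 0.995)
  set_pi("microglia", "Itgam", 0.80)
  set_pi("microglia", "Ptprc", 0.60)
  set_pi("microglia", "Trem2", 0.50)
  set_pi("microglia", "Ccr5", 0.30)

  # oligodendrocyte: Mbp+ with Acta2/Aldoc/Kcnj8/Laptm5 absent
  set_pi("oligodendrocyte", c(rules$oligo_negative, "Gfap", "Gja1", "Aqp4",
                              "S1pr1", "Itgam", "Dcn"), negative)
  set_pi("oligodendrocyte", "Mbp", 0.995)
  set_pi("oligodendrocyte", "Plp1", 0.90)
  set_pi("oligodendrocyte", "Mgll", 0.30)
  set_pi("oligodendrocyte", "Mapt", 0.40)

  # other: vascular-like nonneurons failing the glial gates
  set_pi("other", c("Aldoc", "Laptm5", "Mbp", "Plp1", "Gfap", "Gja1", "Aqp4",
                    "S1pr1", "Itgam"), negative)
  set_pi("other", "Dcn", 0.97)
  set_pi("other", "Acta2", 0.70)
  set_pi("other", "Kcnj8", 0.50)
  set_pi("other", "Cav1", 0.50)

  pi
}

#' Genes used as designed "restored" effects in the default cohort
#' @return Character vector of 12 panel genes outside every marker rule.
#' @export
default_restored_genes <- function() {
  c("Bdnf", "Wfs1", "Grin1", "Nefh", "Ntrk2", "Gls",
    "Arc", "Atf4", "Npy2r", "Reln", "Pcp4", "Scn2a")
}

#' Build a synthetic-cohort generator configuration
#'
#' The defaults emulate the study design the analysis assumes: four groups
#' (C-NB, T-NB, C-NBF, T-NBF) of three samples from two subjects each,
#' six region polygons per sample, homogeneous Poisson cell placement with
#' the highest density in the DG, Bernoulli detection x shifted-Poisson
#' counts over the 158-gene panel with rule-conforming type profiles, and a
#' designed "restored" effect: the twelve [default_restored_genes()] have
#' baseline detection probability `restored_base` in excitatory neurons and
#' are shifted multiplicatively (x `restored_effect`) in the C-NBF group in
#' the EC, leaving C-NB and T-NBF at baseline — the expression pattern the
#' restoration caller is designed to detect.
#'
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration including this seed.
#' @param samples_per_group Samples per group (default 3).
#' @param groups Group labels.
#' @param region_polygons Named list of polygons (SGL nested in DG).
#' @param intensity Named cells-per-mm^2 vector for the exclusive regions.
#' @param placement `"poisson"` or `"thomas"`; Thomas uses `thomas_kappa`
#'   parents/mm^2, `thomas_mu` mean offspring per parent, and
#'   `thomas_sigma` (micrometre) cluster spread.
#' @param thomas_kappa,thomas_mu,thomas_sigma Thomas process parameters.
#' @param mixtures Named list of per-region cell-type probability vectors.
#' @param sgl_mixture Mixture used for DG cells falling inside the SGL
#'   polygon (the only place immature neurons are generated).
#' @param profiles Detection-probability matrix from [default_profiles()].
#' @param restored_genes,restored_effect,restored_base,restored_cell_type,restored_region
#'   Designed restored-gene effect (set `restored_genes = character(0)` for
#'   a null cohort with no group effects).
#' @param effects Optional extra effects tibble with columns `gene`,
#'   `cell_type`, `region`, `group`, `shift` (multiplies pi, clamped to 1).
#' @param mu_counts Mean spot count for a detected gene (counts are
#'   1 + Poisson(mu_counts - 1), so detected genes always have >= 1 spot).
#' @param spot_radius Spots are scattered uniformly in a disc of this
#'   radius (micrometres) around the cell centroid.
#' @param pi_scale Global multiplier on all detection probabilities
#'   (set by [tune_unique_genes()]; clamped into [0, 1] with a message).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             samples_per_group = 3L,
                             groups = group_levels(),
                             region_polygons = default_region_polygons(),
                             intensity = c(CA1 = 1800, CA2 = 1800, CA3 = 1800,
                                           DG = 2500, EC = 1200),
                             placement = c("poisson", "thomas"),
                             thomas_kappa = 30, thomas_mu = 40,
                             thomas_sigma = 50,
                             mixtures = NULL, sgl_mixture = NULL,
                             profiles = default_profiles(),
                             restored_genes = default_restored_genes(),
                             restored_effect = 2.5,
                             restored_base = 0.10,
                             restored_cell_type = "excitatory",
                             restored_region = "EC",
                             effects = NULL,
                             mu_counts = 2, spot_radius = 5,
                             pi_scale = 1) {
  placement <- match.arg(placement)
  types <- cell_type_levels()
  base_mix <- c(immature = 0, excitatory = 0.62, inhibitory = 0.08,
                astrocyte = 0.10, microglia = 0.04,
                oligodendrocyte = 0.12, other = 0.04)[types]
  if (is.null(mixtures)) {
    mixtures <- list(CA1 = base_mix, CA2 = base_mix, CA3 = base_mix,
                     DG = base_mix, EC = base_mix)
  }
  if (is.null(sgl_mixture)) {
    sgl_mixture <- c(immature = 0.40, excitatory = 0.30, inhibitory = 0.05,
                     astrocyte = 0.10, microglia = 0.05,
                     oligodendrocyte = 0.05, other = 0.05)[types]
  }
  for (m in c(mixtures, list(sgl_mixture))) {
    stopifnot(all(m >= 0), abs(sum(m) - 1) < 1e-8)
  }
  stopifnot(all(intensity > 0), all(profiles >= 0), all(profiles <= 1),
            mu_counts >= 1, pi_scale >= 0)
  for (reg in names(region_polygons)) {
    if (polygon_area(region_polygons[[reg]]) <= 0) {
      stop("region ", reg, " has zero area")
    }
  }
  if (length(restored_genes)) {
    profiles[restored_cell_type, restored_genes] <- restored_base
  }
  base_effects <- if (length(restored_genes)) {
    tibble::tibble(gene = restored_genes, cell_type = restored_cell_type,
                   region = restored_region, group = "C-NBF",
                   shift = restored_effect)
  } else {
    tibble::tibble(gene = character(), cell_type = character(),
                   region = character(), group = character(),
                   shift = numeric())
  }
  if (!is.null(effects)) base_effects <- dplyr::bind_rows(base_effects, effects)
  structure(list(
    seed = as.integer(seed), samples_per_group = as.integer(samples_per_group),
    groups = groups, region_polygons = region_polygons,
    intensity = intensity, placement = placement,
    thomas_kappa = thomas_kappa, thomas_mu = thomas_mu,
    thomas_sigma = thomas_sigma,
    mixtures = mixtures, sgl_mixture = sgl_mixture,
    profiles = profiles, effects = base_effects,
    restored_genes = restored_genes,
    mu_counts = mu_counts, spot_radius = spot_radius, pi_scale = pi_scale
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> seed ", x$seed, ", ",
      length(x$groups), " groups x ", x$samples_per_group, " samples, ",
      x$placement, " placement\n", sep = "")
  invisible(x)
}

#' Sample a homogeneous Poisson point pattern inside a polygon
#'
#' @param lambda Intensity (points per mm^2).
#' @param vertices Polygon vertex matrix (micrometre coordinates).
#' @return Two-column matrix of point coordinates.
#' @export
rpoly_poisson <- function(lambda, vertices) {
  area_mm2 <- polygon_area(vertices) / 1e6
  n <- stats::rpois(1, lambda * area_mm2)
  sample_in_polygon(n, vertices)
}

#' Sample a Thomas cluster process inside a polygon
#'
#' Parents are homogeneous Poisson (`kappa` per mm^2) in the polygon's
#' bounding box; each parent gets Poisson(`mu`) offspring displaced by
#' isotropic Gaussian noise with SD `sigma` micrometres; offspring outside
#' the polygon are discarded.
#'
#' @param kappa Parent intensity (per mm^2).
#' @param mu Mean offspring per parent.
#' @param sigma Cluster spread (micrometres).
#' @param vertices Polygon vertex matrix.
#' @return Two-column matrix of retained offspring coordinates.
#' @export
rpoly_thomas <- function(kappa, mu, sigma, vertices) {
  bb <- apply(as.matrix(vertices), 2, range)
  bb_area_mm2 <- prod(bb[2, ] - bb[1, ]) / 1e6
  n_par <- stats::rpois(1, kappa * bb_area_mm2)
  if (n_par == 0) return(matrix(numeric(0), ncol = 2))
  px <- stats::runif(n_par, bb[1, 1], bb[2, 1])
  py <- stats::runif(n_par, bb[1, 2], bb[2, 2])
  n_off <- stats::rpois(n_par, mu)
  ox <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  oy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  keep <- point_in_polygon(ox, oy, vertices)
  cbind(ox[keep], oy[keep])
}

sample_in_polygon <- function(n, vertices) {
  vertices <- as.matrix(vertices)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  bb <- apply(vertices, 2, range)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cx <- stats::runif(m, bb[1, 1], bb[2, 1])
    cy <- stats::runif(m, bb[1, 2], bb[2, 2])
    keep <- point_in_polygon(cx, cy, vertices)
    out <- rbind(out, cbind(cx[keep], cy[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic cohort
#'
#' Produces, for every sample of every group: a decoded-spot table, the
#' region mask set, sample metadata, and ground truth (true cell types,
#' regions, the detection-probability design per group, and the designed
#' restored-gene list). The cohort is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config A [generator_config()].
#' @return List with elements `spots` (named list of spot tibbles),
#'   `masks` (mask-set tibble), `metadata` (tibble), `truth` (list with
#'   `cells`, `profiles`, `effects`, `restored_genes`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  panel <- colnames(config$profiles)
  types <- rownames(config$profiles)
  pi_base <- config$profiles * config$pi_scale
  if (any(pi_base > 1)) {
    message(sum(pi_base > 1), " detection probabilities clamped to 1")
    pi_base[pi_base > 1] <- 1
  }
  sgl_poly <- config$region_polygons[["SGL"]]
  excl_regions <- setdiff(names(config$region_polygons), "SGL")

  metadata <- tidyr::expand_grid(group = config$groups,
                                 rep = seq_len(config$samples_per_group)) |>
    dplyr::mutate(
      sample_id = paste0(.data$group, "_s", .data$rep),
      subject_id = paste0(.data$group, "_m", ifelse(.data$rep <= 2, 1, 2)),
      hemisphere = ifelse(.data$rep %% 2 == 1, "L", "R")
    ) |>
    dplyr::select("sample_id", "subject_id", "group", "hemisphere")

  polys <- purrr::map(metadata$sample_id,
                      function(sid) config$region_polygons)
  names(polys) <- metadata$sample_id
  masks <- region_masks(polys)

  spots_out <- list()
  truth_cells <- list()
  for (si in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[si]
    grp <- metadata$group[si]
    cent <- list(); regs <- list(); sgl_flag <- list()
    for (reg in excl_regions) {
      poly <- config$region_polygons[[reg]]
      xy <- switch(config$placement,
        poisson = rpoly_poisson(config$intensity[[reg]], poly),
        thomas = rpoly_thomas(config$thomas_kappa, config$thomas_mu,
                              config$thomas_sigma, poly))
      cent[[reg]] <- xy
      regs[[reg]] <- rep(reg, nrow(xy))
      in_sgl <- if (reg == "DG" && !is.null(sgl_poly)) {
        point_in_polygon(xy[, 1], xy[, 2], sgl_poly)
      } else rep(FALSE, nrow(xy))
      sgl_flag[[reg]] <- in_sgl
    }
    xy <- do.call(rbind, cent)
    region <- unlist(regs, use.names = FALSE)
    in_sgl <- unlist(sgl_flag, use.names = FALSE)
    n_cells <- nrow(xy)
    if (n_cells == 0) next

    # draw true types: region mixture, SGL sub-mixture inside the SGL strip
    type <- character(n_cells)
    for (reg in unique(region)) {
      idx <- which(region == reg & !in_sgl)
      if (length(idx)) {
        type[idx] <- sample(types, length(idx), replace = TRUE,
                            prob = config$mixtures[[reg]])
      }
    }
    idx <- which(in_sgl)
    if (length(idx)) {
      type[idx] <- sample(types, length(idx), replace = TRUE,
                          prob = config$sgl_mixture)
    }

    # per-cell detection probabilities: type profile x group/region effects
    pi_cell <- pi_base[type, , drop = FALSE]
    eff <- config$effects[config$effects$group == grp, , drop = FALSE]
    if (nrow(eff)) {
      for (k in seq_len(nrow(eff))) {
        rows <- which(type == eff$cell_type[k] & region == eff$region[k])
        if (length(rows)) {
          p <- pi_cell[rows, eff$gene[k]] * eff$shift[k]
          n_clamp <- sum(p > 1)
          if (n_clamp) message(n_clamp, " shifted probabilities clamped to 1")
          pi_cell[rows, eff$gene[k]] <- pmin(p, 1)
        }
      }
    }

    det <- matrix(stats::runif(length(pi_cell)), nrow = n_cells) < pi_cell
    hits <- which(det, arr.ind = TRUE)
    n_spots <- 1L + stats::rpois(nrow(hits), config$mu_counts - 1)
    cell_of_spot <- rep(unname(hits[, 1]), n_spots)
    gene_of_spot <- rep(unname(hits[, 2]), n_spots)
    r <- config$spot_radius * sqrt(stats::runif(length(cell_of_spot)))
    th <- stats::runif(length(cell_of_spot), 0, 2 * pi)
    spots_out[[sid]] <- tibble::tibble(
      gene = panel[gene_of_spot],
      x = xy[cell_of_spot, 1] + r * cos(th),
      y = xy[cell_of_spot, 2] + r * sin(th),
      cell_id = cell_of_spot,
      sample_id = sid
    ) |> dplyr::arrange(.data$cell_id, .data$gene)
    truth_cells[[sid]] <- tibble::tibble(
      sample_id = sid, cell_id = seq_len(n_cells),
      x = xy[, 1], y = xy[, 2],
      true_type = type, true_region = region, true_in_sgl = in_sgl
    )
  }
  list(
    spots = spots_out,
    masks = masks,
    metadata = metadata,
    truth = list(cells = dplyr::bind_rows(truth_cells),
                 profiles = pi_base,
                 effects = config$effects,
                 restored_genes = config$restored_genes)
  )
}

#' Ingest a generated (or deposit-format) cohort into one cell matrix
#'
#' Convenience wrapper: builds per-sample cell matrices from spot tables,
#' assigns regions from the masks, and concatenates.
#'
#' @param cohort Output of [generate_cohort()], or a list with `spots`,
#'   `masks`, `metadata` in the same shape.
#' @param panel Gene panel.
#' @return A `cell_matrix` covering all samples, regions assigned.
#' @export
ingest_cohort <- function(cohort, panel = gene_panel()) {
  mats <- purrr::imap(cohort$spots, function(sp, sid) {
    meta <- cohort$metadata[cohort$metadata$sample_id == sid, , drop = FALSE]
    build_cell_matrix(sp, meta, panel = panel)
  })
  cm <- concat_samples(unname(mats))
  assign_regions(cm, cohort$masks)
}

#' Calibrate detection probabilities to a target median unique-gene count
#'
#' Scales all detection probabilities by a common factor (bisection over
#' the scale) until the simulated median number of unique genes per cell
#' equals `target_median` exactly. The calibration simulation draws cells
#' from the configured type mixtures and is internally seeded from the
#' config seed, so the returned configuration is deterministic.
#'
#' @param config A [generator_config()].
#' @param target_median Target median unique genes per cell (default 5,
#'   the panel-wide detection depth the pipeline is designed around).
#' @param n_cells Cells per calibration simulation.
#' @param max_scale Largest scale explored.
#' @return The config with `pi_scale` set.
#' @export
tune_unique_genes <- function(config, target_median = 5, n_cells = 4000,
                              max_scale = 20) {
  stopifnot(target_median >= 1)
  types <- rownames(config$profiles)
  # marginal type mixture over regions weighted by expected cell numbers
  w <- purrr::imap_dbl(config$mixtures, function(mix, reg) {
    polygon_area(config$region_polygons[[reg]]) / 1e6 * config$intensity[[reg]]
  })
  mix <- Reduce(`+`, purrr::imap(config$mixtures,
                                 function(m, reg) m * w[[reg]]))
  mix <- mix / sum(mix)
  sim_median <- function(scale) {
    set.seed(config$seed + 777L)
    tt <- sample(types, n_cells, replace = TRUE, prob = mix)
    pi <- pmin(config$profiles[tt, , drop = FALSE] * scale, 1)
    uniq <- rowSums(matrix(stats::runif(length(pi)), nrow = n_cells) < pi)
    stats::median(uniq)
  }
  if (all(config$profiles == 0)) {
    stop("all detection probabilities are zero; achievable median is 0")
  }
  lo <- 0; hi <- 1
  m_hi <- sim_median(hi)
  while (m_hi < target_median && hi < max_scale) {
    lo <- hi; hi <- hi * 2
    m_hi <- sim_median(hi)
  }
  if (m_hi < target_median) {
    stop("target median ", target_median, " unattainable; achievable range ",
         "is [0, ", m_hi, "] up to scale ", max_scale)
  }
  if (sim_median(lo) >= target_median && lo == 0) {
    stop("target median ", target_median, " below achievable range")
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (sim_median(mid) >= target_median) hi <- mid else lo <- mid
  }
  config$pi_scale <- hi
  if (sim_median(hi) != target_median) {
    stop("bisection failed to attain median ", target_median,
         " exactly; nearest achievable medians bracket it")
  }
  config
}
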