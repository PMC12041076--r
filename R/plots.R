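#' Volcano plot of percent-expression DEG results
#'
#' log2 fold change against -log10 q, with the conventional FC > 1.5 and
#' q = 0.05 reference lines; points colored by direction call.
#'
#' @param deg DEG tibble from [fisher_deg()] or [deg_pairwise()].
#' @param alpha Significance reference line on q.
#' @param fc_threshold Fold-change reference lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(deg, alpha = 0.05, fc_threshold = 1.5) {
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$q),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_threshold),
                                       log2(fc_threshold)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#d73027", down = "#4575b4",
                                            ns = "grey70"),
                                 na.value = "grey90") +
    ggplot2::facet_grid(region ~ comparison) +
    ggplot2::labs(x = "log2(fold change)", y = "-log10(q)") +
    ggplot2::theme_minimal()
}

#' Group-mean Ripley L curves with SEM ribbons
#'
#' @param group_curves Output of [group_ripley()].
#' @return A ggplot object (one facet per cell type; the dotted identity
#'   line is the expectation under complete spatial randomness).
#' @export
plot_ripley <- function(group_curves) {
  ggplot2::ggplot(group_curves,
                  ggplot2::aes(x = .data$t, y = .data$mean_L,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_L - .data$sem_L,
                                      ymax = .data$mean_L + .data$sem_L),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::labs(x = "t (µm)", y = "L(t)") +
    ggplot2::theme_minimal()
}

#' Stacked cell-type composition bars
#'
#' @param composition Output of [type_composition()] over region x group.
#' @return A ggplot object.
#' @export
plot_type_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$group, y = .data$proportion,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "proportion of cells") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ripley
#' @param object Output of [group_ripley()].
#' @param ... Unused.
#' @method autoplot grouped_ripley
#' @export
autoplot.grouped_ripley <- function(object, ...) plot_ripley(object)
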