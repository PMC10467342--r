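# ggplot2 figures: depth profiles with depth increasing downward, the
# transition zone as a gray band, and confinement summaries.

#' Plot a steady-state solution
#'
#' Depth profiles of concentrations (and optionally pathway rates), depth on
#' the vertical axis increasing downward, the marine-sediment convention.
#'
#' @param object A `nat_solution`.
#' @param which `"concentrations"`, `"rates"` or `"both"`.
#' @param zone Optional `nat_zone` drawn as a gray band.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nat_solution <- function(object, which = c("both", "concentrations", "rates"),
                                  zone = NULL, ...) {
  which <- match.arg(which)
  long <- tidy(object)
  long <- switch(which,
    concentrations = long[long$type == "concentration", ],
    rates = long[long$type == "rate", ],
    both = long[long$type %in% c("concentration", "rate"), ]
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$depth_m,
                                          colour = .data$quantity))
  if (!is.null(zone)) p <- p + zone_band(zone)
  p +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(ggplot2::vars(.data$type), scales = "free_x") +
    ggplot2::labs(x = "concentration (uM) / rate (uM yr⁻¹)",
                  y = "depth (m below seafloor)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Gray-band layer marking a transition zone
#'
#' @param zone A `nat_zone`.
#' @param fill,alpha Band appearance.
#' @return A ggplot2 annotation layer for depth-profile plots (reversed y).
#' @export
zone_band <- function(zone, fill = "grey60", alpha = 0.4) {
  ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                    ymin = zone$z_top, ymax = zone$z_bottom,
                    fill = fill, alpha = alpha)
}

#' Plot observed points over modeled lines
#'
#' The standard measured-versus-modeled porewater figure: observation dots
#' with the steady-state model as lines, one panel per species.
#'
#' @param observed Long tibble (`species`, `depth_m`, `concentration_uM`).
#' @param solution Optional `nat_solution` supplying the modeled lines.
#' @param zone Optional `nat_zone` drawn as a gray band.
#' @return A ggplot object.
#' @export
plot_profiles <- function(observed, solution = NULL, zone = NULL) {
  p <- ggplot2::ggplot(observed, ggplot2::aes(x = .data$concentration_uM,
                                              y = .data$depth_m))
  if (!is.null(zone)) p <- p + zone_band(zone)
  if (!is.null(solution)) {
    lines <- tidy(solution)
    lines <- lines[lines$type == "concentration" &
                     lines$quantity %in% unique(observed$species), ]
    p <- p + ggplot2::geom_path(
      data = lines,
      ggplot2::aes(x = .data$value, y = .data$depth_m, group = .data$quantity),
      colour = "steelblue")
  }
  p +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), scales = "free_x") +
    ggplot2::labs(x = "concentration (uM)", y = "depth (m below seafloor)") +
    ggplot2::theme_minimal()
}

#' Plot taxon depth distributions against a zone
#'
#' @param abundance Long tibble (`taxon`, `depth_m`, `abundance`).
#' @param zone Optional `nat_zone` drawn as a gray band.
#' @param taxa Optional subset of taxa to show.
#' @return A ggplot object.
#' @export
plot_abundance <- function(abundance, zone = NULL, taxa = NULL) {
  if (!is.null(taxa)) abundance <- abundance[abundance$taxon %in% taxa, ]
  p <- ggplot2::ggplot(abundance, ggplot2::aes(x = .data$abundance,
                                               y = .data$depth_m,
                                               colour = .data$taxon))
  if (!is.null(zone)) p <- p + zone_band(zone)
  p +
    ggplot2::geom_path() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "relative abundance", y = "depth (m below seafloor)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot confinement test results
#'
#' @param object A `nat_confinement` tibble from [confinement_test()].
#' @param ... Unused.
#' @return A ggplot object: confinement index per taxon, annotated with the
#'   permutation p-value.
#' @export
autoplot.nat_confinement <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$taxon)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p = %.3g", .data$p_value)),
                       hjust = -0.05, size = 3) +
    ggplot2::xlim(0, 1.15) +
    ggplot2::labs(x = "confinement index", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
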