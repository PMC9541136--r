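# ggplot2 graphics for the screening heuristics, mirroring the standard
# three-panel presentation: per-period index with uncertainty band,
# periods-sampled map, and log10 density maps per period.

#' Plot a per-period nearest-neighbour screen
#'
#' Index per period with its bootstrap ribbon and the CSR expectation at 1;
#' departures below 1 indicate clustering, above 1 regularity.
#'
#' @param object An `nni_screen` from [nni_by_period()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nni_screen <- function(object, ...) {
  df <- tidy.nni_screen(object)
  df$period_n <- as.integer(sub("^p", "", df$period))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period_n, y = .data$index)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_continuous(breaks = df$period_n, labels = df$period) +
    ggplot2::labs(x = "Period", y = "Nearest-neighbour index",
                  caption = sprintf("%d CSR reference sims, %d bootstrap resamples, %.0f%% interval",
                                    attr(object, "n_ref_sims"),
                                    attr(object, "n_boot"),
                                    100 * attr(object, "level"))) +
    ggplot2::theme_minimal()
}

#' Map the number of periods sampled per grid cell
#'
#' @param psm Tibble from [periods_sampled_map()].
#' @param grid The [grid_spec()] used for binning (places tiles in degrees).
#' @return A ggplot.
#' @export
plot_periods_sampled <- function(psm, grid) {
  df <- dplyr::mutate(
    psm,
    lon = grid$origin_lon + (.data$cell_col + 0.5) * grid$resolution,
    lat = grid$origin_lat + (.data$cell_row + 0.5) * grid$resolution
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$n_periods_sampled)) +
    ggplot2::geom_tile(width = grid$resolution, height = grid$resolution) +
    ggplot2::scale_fill_viridis_c(name = "Periods\nsampled") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Map record density per cell, facetted by period
#'
#' Densities are shown on a log10 scale; cells without records are absent
#' rather than drawn at -Inf.
#'
#' @param dens Tibble from [density_surface()].
#' @param grid The [grid_spec()] used for binning.
#' @return A ggplot.
#' @export
plot_density_surface <- function(dens, grid) {
  df <- dplyr::mutate(
    dens,
    lon = grid$origin_lon + (.data$cell_col + 0.5) * grid$resolution,
    lat = grid$origin_lat + (.data$cell_row + 0.5) * grid$resolution
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$log10_n)) +
    ggplot2::geom_tile(width = grid$resolution, height = grid$resolution) +
    ggplot2::facet_wrap(~period) +
    ggplot2::scale_fill_viridis_c(name = "log10\nrecords") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Plot per-period coverage series
#'
#' Works for [taxon_coverage()] (`frac_taxa`) and [env_coverage()]
#' (`frac_bins`) results.
#'
#' @param x A `taxon_coverage` or `env_coverage` object.
#' @return A ggplot of the coverage fraction per period.
#' @export
plot_coverage <- function(x) {
  df <- x$by_period
  ycol <- if ("frac_taxa" %in% names(df)) "frac_taxa" else "frac_bins"
  ylab <- if (ycol == "frac_taxa") "Fraction of target taxa recorded"
          else "Fraction of environmental bins occupied"
  df$period_n <- as.integer(sub("^p", "", df$period))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period_n, y = .data[[ycol]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = df$period_n, labels = df$period) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Period", y = ylab) +
    ggplot2::theme_minimal()
}
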