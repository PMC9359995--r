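#' Plot aligned, normalized trajectories
#'
#' Mean with an SEM ribbon of a baseline-normalized measurement across cells,
#' on the relative time axis (t = 0 is the onset of the nuclear size change).
#'
#' @param aligned an [align_to_size_change()] result.
#' @param var normalized column to plot (default `"area_norm"`).
#' @return a ggplot object.
#' @export
plot_trajectories <- function(aligned, var = "area_norm") {
  df <- aligned_mean(aligned, var)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_time_min / 60, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to nuclear size change (h)",
                  y = paste("normalized", sub("_norm$", "", var)))
}

#' Plot 1D log-density probability histograms
#'
#' @param pdf_tbl a [density_pdf()] result.
#' @return a ggplot object (one step curve per group).
#' @export
plot_density_pdf <- function(pdf_tbl) {
  ggplot2::ggplot(pdf_tbl, ggplot2::aes(x = .data$bin_mid, y = .data$density,
                                        colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(log[10] ~ "normalized Voronoi density" ~ (nm^-2)),
                  y = "probability density", colour = NULL)
}

#' Plot the 2D radius-by-density probability histogram
#'
#' Probability densities are colour-coded with the conventional display
#' clipping (recorded in the histogram's `color_clip` attribute).
#'
#' @param pdf2_tbl a [radius_density_pdf()] result.
#' @return a ggplot object.
#' @export
plot_radius_density <- function(pdf2_tbl) {
  clip <- attr(pdf2_tbl, "color_clip") %||% c(1e-5, 1e-3)
  df <- mutate(pdf2_tbl,
               fill = pmin(pmax(.data$density, clip[1]), clip[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$d_lo + .data$d_hi) / 2,
                                   y = (.data$r_lo + .data$r_hi) / 2,
                                   fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = "log10", limits = clip) +
    ggplot2::labs(x = expression(log[10] ~ "normalized Voronoi density" ~ (nm^-2)),
                  y = "radius from centre of mass (nm)",
                  fill = "probability\ndensity")
}
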