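# ggplot2 visualisations for the main result types.

#' Plot a ratio track along the genome
#'
#' Binned IP/input ratio with masked regions shaded and landmark positions
#' (oriC, dif) marked.
#'
#' @param ratio A [ratio_track()].
#' @param bin Averaging bin for display (bp).
#' @return A ggplot object.
#' @export
plot_ratio_track <- function(ratio, bin = 10000) {
  sm <- sliding_mean(ratio$values, bin)
  p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$center / 1e6,
                                        y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_vline(xintercept = c(ratio$genome$oriC,
                                       ratio$genome$dif) / 1e6,
                        linetype = "dotted") +
    ggplot2::labs(x = "Genome position (Mb)", y = "IP / input ratio")
  iv <- mask_intervals(ratio)
  if (nrow(iv)) {
    p <- p + ggplot2::geom_rect(
      data = iv, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.5)
  }
  p
}

#' @export
autoplot.ratio_track <- function(object, ...) plot_ratio_track(object, ...)

#' Plot the strand-resolved signal around a site
#'
#' Forward and reverse coverage in a window around a (candidate) cleavage
#' or binding site, with the site center marked — the canonical NorflIP
#' shape is a forward block, a gap, and a reverse block.
#'
#' @param profile A [stranded_profile()].
#' @param center 0-based site center.
#' @param window Window width in bp.
#' @param smooth Display smoothing (bp; 1 = raw).
#' @return A ggplot object.
#' @export
plot_site_shape <- function(profile, center, window = 1200, smooth = 20) {
  len <- profile$genome$length
  idx <- window_idx(center - window %/% 2L, as.integer(window), len)
  f <- profile$fwd[idx]; r <- profile$rev[idx]
  if (smooth > 1) {
    f <- smooth_circular(f, smooth); r <- smooth_circular(r, smooth)
  }
  df <- tibble(offset = rep(seq.int(-(window %/% 2L),
                                    window %/% 2L - 1L), 2),
               signal = c(f, r),
               strand = rep(c("forward", "reverse"), each = window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$signal,
                                   color = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(forward = "#D55E00",
                                           reverse = "#0072B2")) +
    ggplot2::labs(x = sprintf("Offset from position %s (bp)",
                              format(center, big.mark = ",")),
                  y = "Coverage")
}

#' Plot a marker-frequency profile with fitted breakpoints
#'
#' @param mf An [marker_frequency()] track.
#' @param fit Optional [detect_slope_breaks()] result; its breakpoints are
#'   drawn as vertical lines.
#' @return A ggplot object.
#' @export
plot_marker_frequency <- function(mf, fit = NULL) {
  df <- tidy(mf)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position / 1e6,
                                        y = .data$marker_frequency)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "Genome position (Mb)", y = "Marker frequency")
  if (!is.null(fit) && length(fit$breakpoints)) {
    p <- p + ggplot2::geom_vline(xintercept = fit$breakpoints / 1e6,
                                 color = "firebrick", linetype = "dashed")
  }
  p
}

#' @export
autoplot.mf_track <- function(object, ...) plot_marker_frequency(object, ...)

#' Plot comet-model occupancy against dosage
#'
#' @param x A [simulate_comet_occupancy()] result.
#' @return A ggplot object with occupancy, dosage, and their ratio.
#' @export
plot_comet_occupancy <- function(x) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(x$track, `occupancy / dosage` =
                    .data$occupancy / .data$dosage),
    -"s", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s / 1e6, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Replichore coordinate (Mb, ori to ter)", y = NULL)
}

#' @export
autoplot.comet_occupancy <- function(object, ...) plot_comet_occupancy(object)

#' Plot site density along the genome
#'
#' @param density A [site_density()] tibble.
#' @return A ggplot object.
#' @export
plot_site_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$start / 1e6,
                                        y = .data$count)) +
    ggplot2::geom_col(width = (density$end[1] - density$start[1]) / 1e6,
                      fill = "grey30") +
    ggplot2::labs(x = "Genome position (Mb)", y = "Sites per bin")
}
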