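# ggplot2 helpers for the main result types.

#' Plot a compartment eigen track
#'
#' Bars above zero are compartment A (gene-dense, GC-rich), below zero B.
#'
#' @param track Labelled track from [orient_and_label()].
#' @param grid The [bin_grid()].
#' @return A ggplot object.
#' @export
plot_compartments <- function(track, grid) {
  df <- track %>%
    left_join(select(grid, "bin", "start"), by = "bin") %>%
    filter(is.finite(.data$eigen))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6, y = .data$eigen,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = grid_resolution(grid) / 1e6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(A = "#d73027", B = "#4575b4"),
                               na.value = "grey70") +
    ggplot2::labs(x = "position (Mb)", y = "eigen value (PC1)",
                  fill = "compartment") +
    ggplot2::theme_minimal()
}

#' Plot an insulation track with TAD boundaries
#'
#' @param track Insulation track from [insulation_score()].
#' @param tads Optional TAD set; boundary bins are marked.
#' @param grid The [bin_grid()].
#' @return A ggplot object.
#' @export
plot_insulation <- function(track, grid, tads = NULL) {
  df <- track %>% left_join(select(grid, "bin", "start"), by = "bin")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                        y = .data$insulation)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "insulation (log2)") +
    ggplot2::theme_minimal()
  if (!is.null(tads) && nrow(tads) > 0) {
    bnd <- tibble(bin = tad_boundaries(tads)) %>%
      left_join(select(grid, "bin", "chrom", "start"), by = "bin")
    p <- p + ggplot2::geom_vline(data = bnd,
                                 ggplot2::aes(xintercept = .data$start / 1e6),
                                 linetype = "dashed", colour = "#d73027")
  }
  p
}

#' Plot a normalized interaction-length profile
#'
#' @param profile Output of [normalized_length_profile()].
#' @return A ggplot object.
#' @export
plot_length_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = (.data$window_lo + .data$window_hi) / 2,
                               y = .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "log10 interaction length (bp)",
                  y = "normalized call count") +
    ggplot2::theme_minimal()
}

#' Plot a 4-bit pattern census
#'
#' @param census Output of [pattern_census()].
#' @param drop_empty Drop codes with zero reads.
#' @return A ggplot object.
#' @export
plot_pattern_census <- function(census, drop_empty = TRUE) {
  df <- if (drop_empty) filter(census, .data$n > 0) else census
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$code, -.data$n),
                                   y = .data$proportion)) +
    ggplot2::geom_col(fill = "#4575b4") +
    ggplot2::labs(x = "pattern code (satI, satII, satIV, telomere)",
                  y = "proportion of reads") +
    ggplot2::theme_minimal()
}

#' Plot the fusion-age gradient
#'
#' @param gradient Output of [age_gradient()].
#' @return A ggplot object.
#' @export
plot_age_gradient <- function(gradient) {
  ggplot2::ggplot(gradient$per_class,
                  ggplot2::aes(x = .data$age_class, y = .data$mean_calls)) +
    ggplot2::geom_col(fill = "#74add1") +
    ggplot2::labs(
      x = "fusion age class (C1 youngest - C5 oldest)",
      y = "mean spanning interactions per fusion site",
      subtitle = sprintf("Pearson r (age rank vs mean) = %.3f",
                         gradient$pearson_r)
    ) +
    ggplot2::theme_minimal()
}

#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, ...) {
  g <- x$grid
  x$counts %>% mutate(
    chrom_i = g$chrom[.data$bin_i], chrom_j = g$chrom[.data$bin_j]
  )
}

#' @method glance bin_map
#' @export
glance.bin_map <- function(x, ...) {
  tibble(
    n_source_bins = n_bins(attr(x, "source_grid")),
    n_mapped = nrow(x),
    mapped_fraction = mapped_fraction(x),
    min_match = attr(x, "min_match")
  )
}
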