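#' Plot a contact-matrix region
#'
#' Heatmap of log1p counts for a genomic window (the full matrix by
#' default; large matrices are best viewed in windows).
#'
#' @param m A `contact_matrix`.
#' @param chrom,from,to Optional region to show (bp).
#' @return A ggplot object.
#' @export
plot_matrix <- function(m, chrom = NULL, from = NULL, to = NULL) {
  bins <- m$bins
  sel <- seq_len(nrow(bins))
  if (!is.null(chrom)) sel <- sel[bins$chrom[sel] == chrom]
  if (!is.null(from)) sel <- sel[bins$end[sel] > from]
  if (!is.null(to)) sel <- sel[bins$start[sel] < to]
  x <- as.matrix(m$counts[sel, sel, drop = FALSE])
  df <- tidyr::expand_grid(i = seq_along(sel), j = seq_along(sel))
  df$value <- log1p(as.vector(x))
  df$pos_i <- bins$start[sel][df$i]
  df$pos_j <- bins$start[sel][df$j]
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_i, .data$pos_j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log1p(counts)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @method autoplot tad_calls
#' @export
autoplot.tad_calls <- function(object, ...) {
  plot_separation_track(object$track,
                        boundaries = filter(object$boundaries,
                                            .data$significant), ...)
}

#' Plot the TAD-separation track with called boundaries
#'
#' @param track A separation-track tibble.
#' @param boundaries Optional boundary tibble to mark (vertical lines).
#' @return A ggplot object.
#' @export
plot_separation_track <- function(track, boundaries = NULL) {
  p <- ggplot2::ggplot(filter(track, .data$valid),
                       ggplot2::aes(.data$start, .data$score)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "TAD-separation score")
  if (!is.null(boundaries) && nrow(boundaries)) {
    p <- p + ggplot2::geom_vline(
      data = boundaries, ggplot2::aes(xintercept = .data$pos),
      colour = "firebrick", linetype = 2)
  }
  p
}

#' Plot the histone-mark separation correlation matrix
#'
#' @param cc Correlation matrix from [histone_separation()].
#' @return A ggplot object.
#' @export
plot_histone_separation <- function(cc) {
  n <- nrow(cc)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$r <- as.vector(cc)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Pearson r") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "scaled TAD bin", y = "scaled TAD bin")
}

#' @method autoplot boundary_model
#' @export
autoplot.boundary_model <- function(object, ...) {
  imp <- tidy(object)
  ggplot2::ggplot(imp, ggplot2::aes(.data$importance,
                                    stats::reorder(.data$feature,
                                                   .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "importance (0-100)", y = NULL)
}
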