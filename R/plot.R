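#' Plot an activation map on a 2D mesh
#'
#' Scatter of vertices coloured by first-activation time, with the split
#' (fibrotic) edges overlaid when a network is given. Requires ggplot2.
#'
#' @param mesh a 2D `dfe_mesh`
#' @param act per-vertex activation times (ms), `NA` for never activated
#' @param network optional `fibrosis_network` drawn as line segments
#' @return a ggplot object
#' @export
plot_activation_map <- function(mesh, act, network = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_activation_map requires the ggplot2 package")
  if (mesh$dim != 2L) stop("plotting is implemented for 2D meshes")
  df <- data.frame(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                   t = act)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$t)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(na.value = "grey85",
                                    name = "activation (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(network) && length(network$faces)) {
    fm <- .key_to_face(network$faces)
    seg <- data.frame(x = mesh$vertices[fm[, 1], 1],
                      y = mesh$vertices[fm[, 1], 2],
                      xend = mesh$vertices[fm[, 2], 1],
                      yend = mesh$vertices[fm[, 2], 2])
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      inherit.aes = FALSE, colour = "black", linewidth = 0.4)
  }
  p
}
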