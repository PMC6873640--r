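# ggplot2 visualisation helpers.

#' Plot a transverse/coronal/sagittal phantom slice
#'
#' @param phantom a `voxel_phantom`.
#' @param axis slicing axis (`"z"` transverse, `"y"` coronal, `"x"`
#'   sagittal).
#' @param index slice index (defaults to the middle slice).
#' @return a ggplot object.
#' @export
plot_phantom_slice <- function(phantom, axis = c("z", "y", "x"),
                               index = NULL) {
  axis <- match.arg(axis)
  d <- dim(phantom$labels)
  ax <- match(axis, c("x", "y", "z"))
  if (is.null(index)) index <- as.integer(round(d[ax] / 2))
  sl <- switch(axis,
               z = phantom$labels[, , index],
               y = phantom$labels[, index, ],
               x = phantom$labels[index, , ])
  df <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$organ <- factor(names(phantom$label_names)[match(as.vector(sl),
                                                      phantom$label_names)],
                     levels = names(phantom$label_names))
  ggplot2::ggplot(df, ggplot2::aes(x = i, y = j, fill = organ)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s slice %d @ %.1f mm", axis, index,
                                  phantom$spacing),
                  x = NULL, y = NULL, fill = "organ") +
    ggplot2::theme_minimal()
}

#' Correlation scatter plots of the cohort metrics
#'
#' DFT energy vs impedance, DFT energy vs eta, impedance vs eta across
#' the cohort rows.
#'
#' @param object a `shock_cohort` tibble from [run_cohort()].
#' @param ... ignored.
#' @return a ggplot object (faceted).
#' @export
autoplot.shock_cohort <- function(object, ...) {
  long <- rbind(
    data.frame(pair = "DFT energy (J) ~ impedance (Ohm)",
               x = object$impedance_ohm, y = object$dft_energy_J,
               config = object$config, size = object$size),
    data.frame(pair = "DFT energy (J) ~ eta",
               x = object$eta, y = object$dft_energy_J,
               config = object$config, size = object$size),
    data.frame(pair = "impedance (Ohm) ~ eta",
               x = object$eta, y = object$impedance_ohm,
               config = object$config, size = object$size))
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = y, colour = config, shape = size)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
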