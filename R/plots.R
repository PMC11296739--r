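#' Plot an estimation trace
#'
#' Objective and KL distance against iteration for an [osl_mapem()] fit.
#'
#' @param object A `phantom_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot phantom_fit
autoplot.phantom_fit <- function(object, ...) {
  tr <- object$trace
  long <- rbind(
    data.frame(iter = tr$iter, value = tr$objective, quantity = "objective"),
    data.frame(iter = tr$iter, value = tr$kl, quantity = "KL distance"))
  ggplot2::ggplot(long, ggplot2::aes(x = iter, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "OSL MAP-EM estimation trace")
}

#' Plot a phantom slice
#'
#' Raster view of one axial slice of a phantom volume.
#'
#' @param object A `phantom_volume`.
#' @param slice Axial slice index (default: middle).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot phantom_volume
autoplot.phantom_volume <- function(object, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(object$grid$shape[3] / 2)
  sl <- object$activity[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$activity <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = activity)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0("phantom activity, slice ", slice))
}

#' @rdname autoplot.phantom_fit
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
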