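# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a GLCV segmentation
#'
#' @param x a `glcv_fit` from [glcv_segment()].
#' @param ... unused.
#' @return The contour tibble with a `part` column.
#' @export
tidy.glcv_fit <- function(x, ...) {
  dplyr::mutate(x$contour, part = "contour")
}

#' One-row summary of a GLCV segmentation
#'
#' @param x a `glcv_fit`.
#' @param ... unused.
#' @return A one-row tibble: iterations, convergence flag, foreground area,
#'   contour length and final monitored energy.
#' @export
glance.glcv_fit <- function(x, ...) {
  P <- contour_points(x$contour)
  nxt <- P[c(2:nrow(P), 1L), ]
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 area_px = sum(x$mask),
                 perimeter_px = sum(sqrt(rowSums((nxt - P)^2))),
                 energy = tail(x$energy, 1L) %||% NA_real_)
}

#' Tidy a motion-model fit
#'
#' @param x a `motion_fit` from [estimate_parameters()].
#' @param ... unused.
#' @return The parameter table (name, estimate, free flag, bounds).
#' @export
tidy.motion_fit <- function(x, ...) {
  dplyr::rename(x$parameters, estimate = "value")
}

#' One-row summary of a motion-model fit
#'
#' @param x a `motion_fit`.
#' @param ... unused.
#' @return A one-row tibble: free-parameter count, forward-simulation
#'   count, max/mean training discrepancy and the threshold.
#' @export
glance.motion_fit <- function(x, ...) {
  tibble::tibble(n_free = sum(x$parameters$free), n_sims = x$n_sims,
                 max_S = max(x$S_final), mean_S = mean(x$S_final),
                 T_threshold = x$T_threshold,
                 all_accepted = all(x$S_final <= x$T_threshold))
}

matrix_to_raster_df <- function(m, value = "value") {
  df <- expand.grid(y = seq_len(nrow(m)) - 1L, x = seq_len(ncol(m)) - 1L)
  df[[value]] <- as.vector(m)
  df
}

#' Plot a segmentation over its image
#'
#' @param object a `glcv_fit`.
#' @param image optional intensity matrix to underlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.glcv_fit <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    p <- p + ggplot2::geom_raster(
      data = matrix_to_raster_df(image),
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  p + ggplot2::geom_path(
    data = rbind(object$contour, object$contour[1L, ]),
    ggplot2::aes(x = .data$x, y = .data$y), colour = "red", linewidth = 0.6) +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot the discrepancy trace of a motion fit
#'
#' @param object a `motion_fit`.
#' @param ... unused.
#' @return A ggplot object showing `S_t` per frame against the threshold.
#' @export
autoplot.motion_fit <- function(object, ...) {
  df <- tibble::tibble(t = seq_along(object$S_final), S_t = object$S_final)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$S_t)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$T_threshold, linetype = 2) +
    ggplot2::labs(x = "training frame", y = "S_t (px)",
                  title = "Training discrepancies vs acceptance threshold")
}

#' Plot a contour series
#'
#' @param contours contour-series tibble (`frame`, `x`, `y`).
#' @param truth optional second series to overlay.
#' @return A ggplot object, one facet per frame.
#' @export
plot_contour_series <- function(contours, truth = NULL) {
  p <- ggplot2::ggplot(contours,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$frame)) +
    ggplot2::geom_path(colour = "red") +
    ggplot2::facet_wrap(~frame) + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_path(data = truth, colour = "darkgreen",
                                linetype = 2)
  }
  p
}

#' Plot a phantom image with its ground-truth contour
#'
#' @param object a `phantom` from [generate_phantom()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phantom <- function(object, ...) {
  ctr <- mask_to_contour(object$mask)
  autoplot.glcv_fit(list(contour = ctr), image = object$image)
}
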