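# Plotting methods. Each result type draws the figure a reader would expect
# next to the numbers: FRAP curves with their fit, per-track dynamics
# distributions, and centerline overlays for segmentation QC.

#' @describeIn fit_recovery plot the curve, the bleach, and the fitted
#'   recovery model.
#' @param object a `frap_fit`.
#' @param ... unused.
#' @export
autoplot.frap_fit <- function(object, ...) {
  cv <- object$curve
  b <- object$bleach_index
  t0 <- cv$time_s[b]
  tt <- seq(t0, max(cv$time_s), length.out = 200)
  fit_df <- tibble(
    time_s = tt,
    intensity = object$F0 + (object$F_inf - object$F0) *
      (1 - exp(-(tt - t0) / object$tau_s)))
  ggplot2::ggplot(cv, ggplot2::aes(.data$time_s, .data$intensity)) +
    ggplot2::geom_vline(xintercept = t0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = object$F_pre, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(data = fit_df, colour = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time (s)", y = "ROI mean intensity",
      title = sprintf("FRAP fit: mobile fraction %.2f, tau %.0f s",
                      object$mobile_fraction, object$tau_s)) +
    ggplot2::theme_minimal()
}

#' @describeIn summarize_dynamics plot the per-track metric distributions.
#' @param object a `dynamics_summary`.
#' @param ... unused.
#' @export
autoplot.dynamics_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$tracks,
    c("dynamic_range_pct", "net_displacement_um", "path_length_um",
      "directionality"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free", nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-track morphology dynamics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Overlay extracted centerlines on a frame
#'
#' Segmentation quality-control figure: the intensity frame with each
#' object's centerline path drawn on top.
#'
#' @param frame numeric Y x X matrix.
#' @param centerlines tibble with a `path` list column (e.g. one frame of
#'   [segment_movie()] output).
#' @return a ggplot.
#' @export
plot_centerlines <- function(frame, centerlines) {
  img_df <- tibble(
    y = rep(seq_len(nrow(frame)), ncol(frame)),
    x = rep(seq_len(ncol(frame)), each = nrow(frame)),
    intensity = as.vector(frame))
  path_df <- purrr::map_dfr(seq_len(nrow(centerlines)), function(i) {
    p <- centerlines$path[[i]]
    tibble(object = i, y = p[, 1], x = p[, 2], ord = seq_len(nrow(p)))
  })
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = img_df,
                         ggplot2::aes(.data$x, .data$y,
                                      fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_path(data = path_df,
                       ggplot2::aes(.data$x, .data$y,
                                    group = .data$object,
                                    colour = factor(.data$object)),
                       linewidth = 0.4, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
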