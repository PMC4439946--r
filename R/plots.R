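#' Overlay DVH curves
#'
#' @param curves named list of [compute_dvh()] curves (names become the
#'   legend labels).
#' @return a ggplot object.
#' @export
plot_dvh <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(as.data.frame(curves[[nm]]), curve = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$volume,
                                   color = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of dose-volume variation
#'
#' @param reports named list of [variation_report()]s (e.g. `org`, `em`).
#' @return a ggplot object.
#' @export
plot_variation <- function(reports) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    cbind(as.data.frame(reports[[nm]]), plan = nm)
  }))
  df$label <- paste(df$structure, df$metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label,
                                   y = .data$variation_pct,
                                   fill = .data$plan)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Variation (% of prescription)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
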