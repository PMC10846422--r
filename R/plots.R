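#' Plot the percentage of GBM remaining over treatment time
#'
#' @param object a `treatment_result`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.treatment_result <- function(object, ...) {
  df <- object$series
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 60,
                                   y = .data$pct_gbm_remaining)) +
    ggplot2::geom_line(color = "#2c7fb8", linewidth = 0.8) +
    ggplot2::labs(x = "time (min)", y = "GBM remaining (%)",
                  title = "PDT cell kill over treatment") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot the maximum-temperature trace
#'
#' Saw-tooth under fractionation: heating during light-on, cooling in the
#' breaks; the 48 C damage threshold is drawn as a dashed line.
#'
#' @param tg a `temperature_grid` (or a `treatment_result` with one)
#' @param damage_T damage threshold, C
#' @return a ggplot
#' @export
plot_max_temperature <- function(tg, damage_T = 48) {
  if (inherits(tg, "treatment_result")) tg <- tg$temperature
  stopifnot(inherits(tg, "temperature_grid"))
  ggplot2::ggplot(tg$max_trace, ggplot2::aes(x = .data$t / 60,
                                             y = .data$max_T)) +
    ggplot2::geom_line(color = "#d95f02", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = damage_T, linetype = "dashed") +
    ggplot2::labs(x = "time (min)", y = "max temperature (C)",
                  title = "Maximum tissue temperature") +
    ggplot2::theme_minimal()
}

#' Heatmap of a fluence or temperature slice
#'
#' @param x a `fluence_grid`, `temperature_grid`, or 3-D array
#' @param k slice index along z (default: middle)
#' @param trans scale transform for the fill (fluence defaults to log10)
#' @return a ggplot
#' @export
plot_slice <- function(x, k = NULL, trans = NULL) {
  arr <- if (inherits(x, "fluence_grid")) x$psi
         else if (inherits(x, "temperature_grid")) x$T
         else x
  if (is.null(trans)) trans <- if (inherits(x, "fluence_grid")) "log10" else "identity"
  if (is.null(k)) k <- ceiling(dim(arr)[3] / 2)
  sl <- arr[, , k]
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- sl[cbind(df$i, df$j)]
  if (identical(trans, "log10")) df$value[df$value <= 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x voxel", y = "y voxel", fill = "value") +
    ggplot2::theme_minimal()
}

#' Plot a sweep comparison
#'
#' End-of-treatment % GBM remaining against the swept value.
#'
#' @param sweep tibble from [run_sweep()]
#' @return a ggplot
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$value,
                                      y = .data$pct_gbm_remaining)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = unique(sweep$axis), y = "GBM remaining (%)",
                  title = "Protocol sweep") +
    ggplot2::theme_minimal()
}
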