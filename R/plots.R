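#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a terazosin dose-response
#'
#' Percent change in ATP production against terazosin concentration on a
#' log axis (the zero-terazosin baseline row is shown as the dashed
#' reference line at 0%).
#'
#' @param object A `tz_dose_response` from [dose_response()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tz_dose_response <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$tz_uM > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$tz_uM, .data$percent_change)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "terazosin (uM)",
                  y = "ATP production change vs no TZ (%)") +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep as a stimulation/inhibition heat map
#'
#' Production ratio (with terazosin / without) across the swept parameter
#' and the terazosin grid; ratios above one (stimulation) in red, below one
#' (inhibition) in blue, one (no effect) in white.
#'
#' @param object A `tz_sweep` from [sweep_parameter()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tz_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$tz_f <- factor(df$tz_uM, levels = sort(unique(df$tz_uM)))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$tz_f,
                                   fill = log2(.data$ratio))) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "white",
                                  high = "red3", midpoint = 0,
                                  name = "log2 ratio") +
    ggplot2::labs(x = unique(df$param), y = "terazosin (uM)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic assay dataset, optionally with its fit
#'
#' @param object An `assay_dataset` from [generate_assay()].
#' @param fit Optional `mm_fit` whose curve is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assay_dataset <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$substrate, .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "substrate", y = "initial rate") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    grid <- tibble::tibble(
      substrate = exp(seq(log(min(object$substrate)),
                          log(max(object$substrate)), length.out = 100))
    )
    grid$rate <- co[["vmax"]] * grid$substrate / (co[["km"]] + grid$substrate)
    p <- p + ggplot2::geom_line(data = grid, colour = "red3")
  }
  p
}

#' @export
plot.tz_dose_response <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.tz_sweep <- function(x, ...) print(autoplot(x, ...))
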