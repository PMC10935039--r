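#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs theme_minimal geom_hline geom_boxplot vars
NULL

#' @export
ggplot2::autoplot

#' Plot the modes of a VMD decomposition
#'
#' One panel per mode, labelled with its centre frequency.
#'
#' @param object A `vmd_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vmd_result <- function(object, ...) {
  df <- tidy(object)
  df$panel <- sprintf("mode %d (%.1f Hz)", df$mode, df$omega_hz)
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(vars(.data$panel), ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "amplitude (µV)") +
    theme_minimal()
}

#' Plot a GA fitness trajectory
#'
#' Best-so-far and generation-mean fitness against generation number.
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fitness_history,
                            cols = c("best", "mean"),
                            names_to = "series", values_to = "fitness")
  ggplot(df, aes(x = .data$generation, y = .data$fitness,
                 colour = .data$series)) +
    geom_line() +
    labs(x = "generation", y = "fitness (mode ApEn)", colour = NULL) +
    theme_minimal()
}

#' Plot per-source approximate entropy from a denoising report
#'
#' Each denoised segment's source ApEn values against the rejection
#' threshold.
#'
#' @param object A `denoise_report` from [denoise_recording()].
#' @param threshold Threshold line to draw (default 0.4).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.denoise_report <- function(object, threshold = 0.4, ...) {
  df <- object |>
    dplyr::filter(.data$denoised) |>
    dplyr::select("segment", "apen") |>
    tidyr::unnest("apen")
  ggplot(df, aes(x = factor(.data$segment), y = .data$apen)) +
    geom_point() +
    geom_hline(yintercept = threshold, linetype = 2) +
    labs(x = "segment", y = "source ApEn") +
    theme_minimal()
}

#' Plot an SNR-sweep benchmark
#'
#' Correlation and relative RMSE of mixture and cleaned signal against
#' the clean reference, per SNR level.
#'
#' @param sweep Tibble from [evaluate_snr_sweep()].
#' @return A ggplot.
#' @export
plot_snr_sweep <- function(sweep) {
  df <- sweep |>
    dplyr::select("snr", "cc_mixed", "cc_cleaned",
                  "rrmse_mixed", "rrmse_cleaned") |>
    tidyr::pivot_longer(-"snr", names_to = c("metric", "stage"),
                        names_sep = "_", values_to = "value")
  ggplot(df, aes(x = factor(.data$snr), y = .data$value,
                 colour = .data$stage)) +
    geom_boxplot() +
    facet_wrap(vars(.data$metric), scales = "free_y") +
    labs(x = "SNR", y = NULL, colour = NULL) +
    theme_minimal()
}
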