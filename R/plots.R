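#' Plot an evaluation report
#'
#' Per-class and total accuracy with Monte-Carlo error bars, one panel per
#' phase.
#'
#' @param object An `mw_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mw_eval <- function(object, ...) {
  agg <- summary_eval(object)
  acc_cols <- grep("^(total_accuracy|acc_).*_mean$", names(agg), value = TRUE)
  long <- agg |>
    dplyr::select("phase", dplyr::all_of(c(acc_cols, sub("_mean$", "_sd", acc_cols)))) |>
    tidyr::pivot_longer(-"phase",
                        names_to = c("metric", ".value"),
                        names_pattern = "(.*)_(mean|sd)$") |>
    dplyr::mutate(metric = sub("^acc_", "", sub("^total_accuracy$", "total",
                                                .data$metric)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "accuracy",
                  title = paste(object$classifier$family, "on",
                                object$response)) +
    ggplot2::theme_minimal()
}

#' Plot a sub-band search
#'
#' Held-out balance rate (lower is better) per sub-band mask, in ranked
#' order, with total accuracy overlaid as text.
#'
#' @param object An `mw_subband_search` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mw_subband_search <- function(object, ...) {
  test <- object |> dplyr::filter(.data$phase == "test") |>
    dplyr::mutate(mask = factor(.data$mask, levels = rev(unique(.data$mask))))
  ggplot2::ggplot(test, ggplot2::aes(x = .data$balance_rate_mean, y = .data$mask)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$balance_rate_mean - .data$balance_rate_sd,
      xmax = .data$balance_rate_mean + .data$balance_rate_sd), height = 0.2) +
    ggplot2::labs(x = "balance rate (test)", y = "sub-band mask") +
    ggplot2::theme_minimal()
}

#' Plot spatial magnitude profiles of scans
#'
#' `|S21|` against receiver angle at a chosen frequency, one line per scan,
#' coloured by density label; useful for eyeballing the smoother LD versus
#' richer HD angular structure.
#'
#' @param scans A list of [s21_scan()] objects.
#' @param f_hz Frequency on the scan grid (default 4 GHz).
#' @param tx Transmitter block to show (default 1).
#' @return A ggplot.
#' @export
plot_spatial_profiles <- function(scans, f_hz = 4e9, tx = 1L) {
  rows <- lapply(scans, function(s) {
    col <- freq_col_index(f_hz, s$geometry)
    idx <- ((tx - 1) * s$geometry$n_rx + 1):(tx * s$geometry$n_rx)
    tibble::tibble(sample_id = s$sample_id, density = s$density_label,
                   angle_deg = rx_angles(s$geometry),
                   magnitude = Mod(s$matrix[idx, col]))
  })
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, y = .data$magnitude,
                                   group = .data$sample_id,
                                   colour = .data$density)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "receiver angle (deg)", y = "|S21|",
                  title = sprintf("Spatial profiles at %.0f GHz, Tx %d",
                                  f_hz / 1e9, tx)) +
    ggplot2::theme_minimal()
}
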