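#' Plot an impedance spectrum
#'
#' Resistance and reactance against oscillation frequency in two panels.
#' When the reactance crosses zero inside the grid, the reactance-area
#' region (between 5 Hz, the reactance curve and its zero crossing) is
#' shaded — the classic "triangle" visualisation of AX.
#'
#' @param object An [ios_spectrum()].
#' @param shade_ax Shade the reactance area (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ios_spectrum <- function(object, shade_ax = TRUE, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("resistance", "reactance"),
                              names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$frequency, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "impedance (kPa·s/L)")
  fres <- compute_fres(object)
  x5 <- tryCatch(value_at(object, 5, "reactance"), error = function(e) NA_real_)
  if (shade_ax && !is.na(fres) && !is.na(x5) && x5 < 0 && fres > 5) {
    grid_f <- sort(unique(c(5, object$frequency[object$frequency > 5 &
                                                  object$frequency < fres], fres)))
    shade <- tibble::tibble(frequency = grid_f,
                            value = c(x5, value_at(object, grid_f[-c(1, length(grid_f))],
                                                   "reactance"), 0),
                            channel = "reactance")
    p <- p + ggplot2::geom_ribbon(
      data = shade, ggplot2::aes(ymin = .data$value, ymax = 0),
      fill = "steelblue", alpha = 0.3)
  }
  p
}

#' Plot a circuit fit against its measured spectrum
#'
#' Measured resistance/reactance as points and the fitted model curve,
#' evaluated on a dense grid, as lines.
#'
#' @param object An `ios_fit` from [fit_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ios_fit <- function(object, ...) {
  meas <- tidyr::pivot_longer(tibble::as_tibble(object$spectrum),
                              c("resistance", "reactance"),
                              names_to = "channel", values_to = "value")
  dense_f <- exp(seq(log(min(object$spectrum$frequency)),
                     log(max(object$spectrum$frequency)), length.out = 200))
  curve <- eval_model(object$model, object$parameters, dense_f)
  mod <- tidyr::pivot_longer(tibble::as_tibble(curve),
                             c("resistance", "reactance"),
                             names_to = "channel", values_to = "value")
  ggplot2::ggplot(meas, ggplot2::aes(x = .data$frequency, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(data = mod, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "impedance (kPa·s/L)",
                  title = sprintf("%s fit, objective %.2e",
                                  object$model, object$objective))
}

#' Scatter plot of group means across study cells
#'
#' Quick visual of a cohort summary: one panel per index/parameter, group
#' means across the three study cells.
#'
#' @param report An `ios_report` from [study_report()].
#' @param parameters Which long-format parameters to show.
#' @return A ggplot object.
#' @export
plot_group_trajectories <- function(report,
                                    parameters = c("r5", "fdr", "ax")) {
  means <- report$summary |>
    dplyr::filter(!duplicated(paste(.data$group, .data$visit, .data$condition))) |>
    tidyr::pivot_longer(dplyr::any_of(parameters),
                        names_to = "parameter", values_to = "value") |>
    dplyr::mutate(cell = factor(paste(.data$visit, .data$condition),
                                levels = cell_levels()))
  ggplot2::ggplot(means, ggplot2::aes(x = .data$cell, y = .data$value,
                                      colour = .data$group,
                                      group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean")
}
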