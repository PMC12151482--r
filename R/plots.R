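#' Plot a stationary concentration law
#'
#' Density curve of the exact stationary law; supply a second law (typically
#' the other perspective) to overlay both.
#'
#' @param object A [stationary_law()].
#' @param other Optional second law to overlay.
#' @param xlim Upper concentration limit (defaults to the 99.9% quantile).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stationary_law <- function(object, other = NULL, xlim = NULL, ...) {
  laws <- c(list(object), if (!is.null(other)) list(other))
  hi <- xlim %||% max(vapply(laws, function(l) qstationary(0.999, l),
                             numeric(1)))
  grid <- seq(0, hi, length.out = 400)
  df <- purrr::map_dfr(laws, function(l) {
    tibble::tibble(x = grid, density = dstationary(grid, l),
                   perspective = l$perspective)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$density,
                                   colour = .data$perspective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "protein concentration", y = "stationary density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot protein noise against cell-cycle noise
#'
#' Visualizes a `cycle_noise_sweep` result table: protein noise `CV^2_x`
#' versus cell-cycle noise `CV^2_tau` for both perspectives, with the
#' analytic single-cell prediction as a horizontal reference.
#'
#' @param stats The `stats` table from
#'   `run_experiment("cycle_noise_sweep", ...)`.
#' @return A ggplot object.
#' @export
plot_cycle_noise <- function(stats) {
  sim <- dplyr::filter(stats, .data$perspective != "analytic_sc")
  ana <- dplyr::filter(stats, .data$perspective == "analytic_sc")
  ggplot2::ggplot(sim, ggplot2::aes(.data$cv2_tau, .data$cv2,
                                    colour = .data$perspective)) +
    ggplot2::geom_hline(yintercept = ana$cv2[1], linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(CV[tau]^2), y = expression(CV[x]^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot noise against mean on log axes
#'
#' Visualizes a `mean_scaling` result table: steady-state protein noise
#' versus mean concentration in both perspectives, log-log.
#'
#' @param stats The `stats` table from `run_experiment("mean_scaling", ...)`.
#' @return A ggplot object.
#' @export
plot_noise_vs_mean <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(.data$target_mean, .data$cv2,
                                      colour = .data$perspective)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean protein concentration", y = expression(CV[x]^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a single-cell trajectory
#'
#' Concentration over time with burst/division events marked.
#'
#' @param trajectory A trajectory tibble from [simulate_lineage_feedback()]
#'   or [simulate_lineage_partitioning()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory) {
  ev <- dplyr::filter(trajectory, !.data$event %in% c("sample", "start"))
  ggplot2::ggplot(trajectory, ggplot2::aes(.data$time, .data$x)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = ev, ggplot2::aes(shape = .data$event),
                        colour = "firebrick", size = 1.5) +
    ggplot2::labs(x = "time", y = "protein concentration", shape = NULL) +
    ggplot2::theme_minimal()
}
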