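#' Plot a closed-loop simulation record
#'
#' Two stacked panels in the style of closed-loop anesthesia reports: the
#' BSP panel shows the true BSP, the estimated BSP and the piecewise
#' target; the infusion panel shows the commanded rate.
#'
#' @param object A `bsp_sim` record from [simulate_closed_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsp_sim <- function(object, ...) {
  d <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(t = d$t, value = d$p_true, series = "true BSP",
                   panel = "BSP"),
    tibble::tibble(t = d$t, value = d$p_hat, series = "estimated BSP",
                   panel = "BSP"),
    tibble::tibble(t = d$t, value = d$target, series = "target",
                   panel = "BSP"),
    tibble::tibble(t = d$t, value = d$u, series = "infusion",
                   panel = "infusion (mg/min)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t / 60, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_step(data = ~ dplyr::filter(.x, .data$series == "target"),
                       linewidth = 0.4) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$series != "target"),
                       linewidth = 0.4, alpha = 0.9) +
    ggplot2::facet_grid(panel ~ ., scales = "free_y", switch = "y") +
    ggplot2::labs(x = "time (min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a PK fit against its target trace
#'
#' @param object A `pk_fit` from [fit_pk()].
#' @param dt Step length in seconds for the time axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_fit <- function(object, dt = object$params$dt, ...) {
  d <- tibble::tibble(
    t = seq_along(object$target) * dt / 60,
    target = object$target,
    fitted = object$fitted_trace
  ) |>
    tidyr::pivot_longer(-"t", names_to = "series", values_to = "bsp")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$bsp,
                                  colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::scale_colour_manual(
      values = c(target = "grey50", fitted = "red")) +
    ggplot2::labs(x = "time (min)", y = "BSP", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Box-summary plot of per-level absolute error
#'
#' Modified boxplot summary of the steady-state absolute error
#' distribution per level: boxes span the 25th-75th percentiles with the
#' median marked, whiskers reach the 95th percentile (the reliability
#' statistic), and the 0.15 / 0.10 reliability thresholds are drawn as
#' reference lines.
#'
#' @param data Steady-state samples with columns `p_hat`, `target` (apply
#'   [steady_state_mask()] first).
#' @return A ggplot object.
#' @export
plot_reliability <- function(data) {
  d <- tibble::tibble(
    level = level_labels(data$target),
    abs_dev = abs(data$p_hat - data$target)
  ) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      q25 = stats::quantile(.data$abs_dev, 0.25, names = FALSE),
      q50 = stats::quantile(.data$abs_dev, 0.50, names = FALSE),
      q75 = stats::quantile(.data$abs_dev, 0.75, names = FALSE),
      q95 = stats::quantile(.data$abs_dev, 0.95, names = FALSE),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q75,
                                         ymax = .data$q95)) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$q50, ymin = .data$q25,
                                        ymax = .data$q75), width = 0.4) +
    ggplot2::geom_hline(yintercept = c(0.10, 0.15), linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "target level", y = "absolute BSP error") +
    ggplot2::theme_minimal()
}
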