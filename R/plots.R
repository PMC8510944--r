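#' Plot pressure traces
#'
#' Overpressure against time, one line per probe.
#'
#' @param trace Trace tibble (`time_s`, `overpressure_pa`, `probe`).
#' @param time_unit `"ms"` or `"s"`.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, time_unit = c("ms", "s")) {
  time_unit <- match.arg(time_unit)
  f <- if (time_unit == "ms") 1e3 else 1
  ggplot2::ggplot(trace, ggplot2::aes(
    x = .data$time_s * f, y = .data$overpressure_pa / 1e3,
    colour = .data$probe
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0("time (", time_unit, ")"),
                  y = "overpressure (kPa)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ternary overpressure map of a snapshot
#'
#' Renders a pressure snapshot with the confined-blast rendering rule:
#' red where overpressure exceeds +30% of ambient, blue below -30%,
#' white between; solid cells grey.
#'
#' @param snapshot A `(time, pressure)` snapshot.
#' @param grid The [axi_grid()] of the run.
#' @param ambient Ambient pressure, Pa.
#' @return A ggplot object.
#' @export
plot_overpressure_map <- function(snapshot, grid, ambient = 101.3e3) {
  cls <- classify_overpressure(snapshot$pressure, ambient)
  d <- tibble::tibble(
    z = rep(grid$z_centers, times = grid$nr),
    r = rep(grid$r_centers, each = grid$nz),
    class = factor(as.vector(cls), levels = c("low", "neutral", "high"))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$r,
                                  fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(low = "#3b6fb6", neutral = "white", high = "#c03a2b"),
      na.value = "grey60", drop = FALSE
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z (m)", y = "r (m)", fill = "overpressure",
                  title = sprintf("t = %.2f ms", snapshot$time * 1e3)) +
    ggplot2::theme_minimal()
}

#' Plot cohort outcomes by group
#'
#' Stacked counts of survival/death within the armor and non-armor groups.
#'
#' @param cohort A cohort tibble.
#' @return A ggplot object.
#' @export
plot_cohort_outcomes <- function(cohort) {
  d <- dplyr::count(cohort,
                    group = ifelse(.data$armor, "armor", "non-armor"),
                    outcome = .data$outcome)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$n,
                                  fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(Survival = "#4c9f70",
                                          Death = "#c03a2b")) +
    ggplot2::labs(x = NULL, y = "animals", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot physiological trajectories
#'
#' Per-variable group-mean trajectories with individual animal lines.
#'
#' @param physiology Long tibble from [generate_physiology()].
#' @param variables Subset of variables to show; `NULL` for all.
#' @return A ggplot object.
#' @export
plot_physiology <- function(physiology, variables = NULL) {
  d <- physiology
  if (!is.null(variables)) d <- d[d$variable %in% variables, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  group = .data$id,
                                  colour = .data$outcome)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~ variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.friedlander_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- as.numeric(stats::fitted(object$fit))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau * 1e3)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p / 1e3), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted / 1e3),
                       colour = "#c03a2b") +
    ggplot2::labs(x = "time from arrival (ms)", y = "overpressure (kPa)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
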