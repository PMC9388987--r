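# ggplot2 views of run and sweep results.

#' Plot pooled processing-time distribution
#'
#' Histogram of patient-level processing times pooled over replications,
#' with the pooled median and 95th percentile marked.
#'
#' @param run A [run_baseline()] result.
#' @param binwidth Histogram bin width in minutes.
#' @return A ggplot object.
#' @export
plot_processing_times <- function(run, binwidth = 2) {
  if (!inherits(run, "vax_run")) {
    abort_config("`run` must come from `run_baseline()`.")
  }
  df <- tibble(processing_time = run$summary$times)
  p <- run$summary$pooled
  ggplot2::ggplot(df, ggplot2::aes(x = .data$processing_time)) +
    ggplot2::geom_histogram(
      binwidth = binwidth, fill = "steelblue", colour = "white"
    ) +
    ggplot2::geom_vline(xintercept = p$median, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = p$p95, linetype = "dotted") +
    ggplot2::labs(
      x = "Processing time (minutes)", y = "Patients",
      title = paste0(
        toupper(run$config$site), " ", run$config$level,
        ": median ", round(p$median, 1), " min, 95th pct ",
        round(p$p95, 1), " min"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vax_run <- function(object, ...) {
  plot_processing_times(object, ...)
}

#' Plot per-station staff utilisation
#'
#' @param run A [run_baseline()] result.
#' @param util_max Reference line (default 0.8, where queue performance
#'   degrades sharply).
#' @return A ggplot object.
#' @export
plot_utilisation <- function(run, util_max = 0.8) {
  if (!inherits(run, "vax_run")) {
    abort_config("`run` must come from `run_baseline()`.")
  }
  df <- run$summary$util
  df$station <- factor(df$station, levels = df$station)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$station, y = .data$mean_utilisation, fill = .data$role)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = util_max, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Mean utilisation / occupancy",
      title = paste0(toupper(run$config$site), " ", run$config$level)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a what-if sweep
#'
#' Median processing time (with the 95th percentile as a ribbon bound)
#' against the swept quantity — extra arrivals per slot or staff removed.
#'
#' @param sweep A [whatif_arrivals()] or [whatif_staff()] result.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  if (!inherits(sweep, "vax_sweep")) {
    abort_config("`sweep` must come from a what-if function.")
  }
  kind <- attr(sweep, "sweep")
  xvar <- if (kind == "arrivals") "extra_per_slot" else "staff_removed"
  xlab <- if (kind == "arrivals") {
    "Additional arrivals per slot"
  } else {
    "Staff removed"
  }
  df <- as_tibble(sweep)
  ggplot2::ggplot(
    dplyr::filter(df, .data$feasible),
    ggplot2::aes(x = .data[[xvar]], y = .data$median)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$median, ymax = .data$p95),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = xlab, y = "Median processing time (minutes)",
      title = paste0(
        toupper(attr(sweep, "site")), " ", attr(sweep, "level"),
        " (ribbon to 95th percentile)"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vax_sweep <- function(object, ...) {
  plot_sweep(object)
}
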