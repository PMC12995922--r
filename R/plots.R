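#' Plot a present-value path
#'
#' The characteristic sawtooth of even-aged management: the present value
#' rises with stand age towards the final harvest and resets afterwards;
#' disturbances appear as off-schedule drops.
#'
#' @param paths Output of [value_paths()].
#' @param regime_id,run,es Which path to draw.
#' @param threshold Optional horizontal reference line.
#' @return A ggplot object.
#' @export
plot_value_path <- function(paths, regime_id, run = 1, es = "financial",
                            threshold = NULL) {
  df <- paths |>
    filter(.data$regime_id == !!regime_id, .data$run == !!run,
           .data$es == !!es)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(colour = "#2c6e49") +
    ggplot2::labs(
      x = "simulation time (yr)",
      y = if (es == "financial") "V (EUR/ha)" else "V (tC/ha)",
      title = sprintf("Present-value path, %s (run %d, %s)",
                      regime_id, run, es)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot recovery-time gain distributions
#'
#' Distributions of per-event recovery-time gains relative to the baseline,
#' coloured by disturbance type; negative gains are net elongations of the
#' recovery process.
#'
#' @param assessment A `standres_assessment`.
#' @param es Ecosystem service to show.
#' @param regimes Optional subset of regime ids.
#' @return A ggplot object.
#' @export
plot_recovery_gains <- function(assessment, es = "financial",
                                regimes = NULL) {
  rec <- assessment$records |>
    filter(.data$es == !!es, !.data$censored) |>
    mutate(type_shown = factor(dplyr::coalesce(.data$type, .data$type_base)))
  if (!is.null(regimes)) rec <- rec |> filter(.data$regime_id %in% regimes)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$gain,
                                    fill = .data$type_shown)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$regime_id)) +
    ggplot2::labs(x = "recovery-time gain vs. baseline (yr)",
                  y = "events", fill = "disturbance type") +
    ggplot2::theme_minimal()
}

#' Plot SEV distributions per regime
#'
#' Soil-expectation-value distributions of all regimes with the baseline
#' mean as reference line.
#'
#' @param assessment A `standres_assessment`.
#' @param es Ecosystem service to show.
#' @return A ggplot object.
#' @export
plot_sev_distributions <- function(assessment, es = "financial") {
  sev <- assessment$sev |> filter(.data$es == !!es)
  base_mean <- sev |>
    filter(.data$regime_id == assessment$baseline_id) |>
    pull("sev") |> mean()
  ggplot2::ggplot(sev, ggplot2::aes(x = .data$regime_id, y = .data$sev)) +
    ggplot2::geom_boxplot(fill = "#a3c9a8") +
    ggplot2::geom_hline(yintercept = base_mean, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = if (es == "financial") "SEV (EUR/ha)" else "SEV (tC/ha)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.standres_assessment <- function(object, es = "financial", ...) {
  df <- object$summary |> filter(.data$es == !!es)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_gain, y = .data$tau,
                                   label = .data$regime_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$dominant), size = 2) +
    ggplot2::geom_text(vjust = -0.6, size = 2.7) +
    ggplot2::labs(
      x = "mean recovery-time gain (yr)",
      y = "trade-off tau (SEV change per yr of gain)",
      colour = "dominant"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.standres_experiment <- function(object, ...) {
  autoplot(object$assessment, ...)
}
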