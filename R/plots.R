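#' @import ggplot2
NULL

#' Plot a trace
#'
#' Facetted time courses of membrane potential, cytosolic Ca2+, active force
#' and cell length.
#'
#' @param object A `cardio_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cardio_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object)[c("time_ms", "V_mV", "Cai_uM", "F_active",
                            "L_frac")],
    -"time_ms", names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal,
                        levels = c("V_mV", "Cai_uM", "F_active", "L_frac"),
                        labels = c("V (mV)", "[Ca2+]i (uM)",
                                   "active force (norm.)", "length (L/Lmax)"))
  ggplot(long, aes(x = .data$time_ms, y = .data$value)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~signal, scales = "free_y", ncol = 1) +
    labs(x = "time (ms)", y = NULL) +
    theme_bw()
}

#' Plot the convergence history of a history-matching run
#'
#' Three panels mirroring the usual convergence diagnostics: surviving-cloud
#' size, survival ratio relative to the previous wave, and simulator
#' acceptance rate per wave.
#'
#' @param state A `wave_state` (or its `history` tibble).
#' @return A ggplot.
#' @export
plot_wave_history <- function(state) {
  hist <- if (inherits(state, "wave_state")) state$history else state
  hist$survival_ratio <- hist$candidates_surviving /
    pmax(hist$candidates_in, 1)
  long <- tidyr::pivot_longer(
    hist[c("wave", "candidates_surviving", "survival_ratio",
           "sim_accept_rate")],
    -"wave", names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("candidates_surviving", "survival_ratio",
                                   "sim_accept_rate"),
                        labels = c("surviving candidates",
                                   "survival ratio",
                                   "simulator acceptance rate"))
  ggplot(long, aes(x = .data$wave, y = .data$value)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "wave", y = NULL) + theme_bw()
}

#' Plot an event heatmap
#'
#' Counts of models with repolarization abnormalities (top number in each
#' cell) and failed contractions (bottom number) over the concentration x
#' initial-length grid.
#'
#' @param object An `event_heatmap` from [drug_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.event_heatmap <- function(object, ...) {
  df <- as.data.frame(object)
  df$label <- sprintf("%d\n%d", df$n_repol_abnormal,
                      df$n_failed_contraction)
  df$frac <- (df$n_repol_abnormal + df$n_failed_contraction) /
    pmax(2 * df$n_total, 1)
  ggplot(df, aes(x = factor(.data$length), y = factor(.data$multiplier))) +
    geom_tile(aes(fill = .data$frac), color = "grey30") +
    geom_text(aes(label = .data$label), size = 3) +
    scale_fill_gradient(low = "white", high = "firebrick",
                        name = "event fraction") +
    labs(x = "initial length (L/Lmax)", y = "concentration (x EFTPCmax)",
         title = unique(df$drug)) +
    theme_bw()
}

#' Boxplots of scaling-factor distributions in a population
#'
#' @param population Population tibble.
#' @param accepted_only Restrict to accepted models.
#' @return A ggplot.
#' @export
plot_population_parameters <- function(population, accepted_only = TRUE) {
  df <- population
  if (accepted_only && "status" %in% names(df))
    df <- df[df$status == "accepted", , drop = FALSE]
  long <- tidyr::pivot_longer(df[intersect(.param_names, colnames(df))],
                              dplyr::everything(),
                              names_to = "parameter", values_to = "factor")
  long$parameter <- factor(long$parameter, levels = .param_names)
  ggplot(long, aes(x = .data$parameter, y = .data$factor)) +
    geom_boxplot(outlier.size = 0.5) +
    geom_hline(yintercept = 1, linetype = 2, color = "grey40") +
    labs(x = NULL, y = "scaling factor") + theme_bw()
}

#' Per-model length-force and force-velocity curves
#'
#' @param report A `mech_stage_report` from [stage_lf_curve()] or
#'   [stage_afterload()] (uses its `lf_curves` / `fv_curves` attribute).
#' @return A ggplot.
#' @export
plot_mech_curves <- function(report) {
  lf <- attr(report, "lf_curves")
  fv <- attr(report, "fv_curves")
  if (!is.null(lf)) {
    ggplot(lf, aes(x = .data$length, y = .data$normalized,
                   group = .data$model_id)) +
      geom_line(alpha = 0.4) + geom_point(size = 0.8, alpha = 0.4) +
      labs(x = "initial length (L/Lmax)",
           y = "peak force (norm. to 0.93 Lmax)") + theme_bw()
  } else if (!is.null(fv)) {
    ggplot(fv, aes(x = .data$afterload, y = .data$max_velocity,
                   group = .data$model_id)) +
      geom_line(alpha = 0.4) + geom_point(size = 0.8, alpha = 0.4) +
      labs(x = "afterload (fraction of F_max)",
           y = "max shortening velocity (Lmax/s)") + theme_bw()
  } else {
    abort("report carries no curves")
  }
}
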