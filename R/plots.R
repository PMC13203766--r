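# ggplot2 visualisations for the main result types.

#' @export
autoplot.hr_series <- function(object, ...) {
  tau <- attr(object, "tau")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t_s, y = .data$hr_bpm)) +
    ggplot2::geom_line(na.rm = TRUE, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "HR (bpm)",
                  title = if (is.na(tau)) "instantaneous HR" else
                    sprintf("HR filtered at tau = %g s", tau)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.epoch_mask <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_s, y = 1,
                                    fill = .data$label)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_manual(values = c(accel = "#2c7fb8",
                                          decel = "#d95f02",
                                          neither = "grey80",
                                          invalid = "white")) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("epochs at tau = %g s",
                                  attr(object, "tau"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.dyad_features <- function(object, ...) {
  crv <- object$curves
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$tau_s, y = .data$value_nats,
                                    colour = .data$paradigm,
                                    linetype = .data$signal)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.7, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::labs(x = "time scale tau (s)", y = "nats") +
    ggplot2::theme_minimal()
}

#' Cohort distribution of one feature by stratum
#'
#' @param features Cohort feature table.
#' @param cohort Cohort table (`dyad_id`, `group`, `sex`).
#' @param feature Feature column name.
#' @return A ggplot.
#' @export
plot_feature_by_group <- function(features, cohort, feature) {
  dat <- dplyr::inner_join(features, cohort, by = "dyad_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data[[feature]],
                                    fill = .data$sex)) +
    ggplot2::geom_boxplot(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}
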