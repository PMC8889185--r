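#' Diagnostic plots for experiment results
#'
#' `autoplot()` methods: transitivity runs are drawn as `t_tri` against
#' density (points per run, coloured by condition); activity runs as
#' boxplots of `t_tri` per rule cell; diffusion runs as boxplots of T50
#' and efficiency on the log scale; a diffusion result as its informed
#' trajectory with T50 marked; a TSP as normalized Z per class.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-colonysim
NULL

#' @rdname autoplot-colonysim
#' @export
autoplot.ttri_runs <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$t_tri)),
                  ggplot2::aes(x = .data$density_target, y = .data$t_tri,
                               colour = .data$condition)) +
    ggplot2::geom_jitter(width = 20, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "network density (binary edges)", y = "triangle transitivity",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-colonysim
#' @export
autoplot.activity_runs <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$t_tri)),
                  ggplot2::aes(x = interaction(.data$initiation, .data$direction,
                                               sep = " init / "),
                               y = .data$t_tri, fill = .data$condition)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "initiation / direction rule", y = "triangle transitivity",
                  fill = "condition") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-colonysim
#' @export
autoplot.diffusion_runs <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object, !is.na(.data$t50)),
    c("log_t50", "log_efficiency"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log-transformed value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot-colonysim
#' @export
autoplot.diffusion_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$trajectory,
                       ggplot2::aes(x = .data$step, y = .data$informed)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dotted") +
    ggplot2::labs(x = "time step", y = "informed agents") +
    ggplot2::theme_minimal()
  if (!is.na(object$t50)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t50, linetype = "dashed")
  }
  p
}

#' Plot a triad significance profile
#'
#' @param profile A tibble from [tsp_profile()], optionally row-bound over
#'   several networks (means and standard errors are drawn per class).
#' @return A ggplot object.
#' @export
plot_tsp <- function(profile) {
  summ <- profile |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      mean_z = mean(.data$z_norm),
      se = sd(.data$z_norm) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = factor(.data$class, levels = triad_classes()))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$class, y = .data$mean_z)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_z - .data$se,
                                          ymax = .data$mean_z + .data$se)) +
    ggplot2::labs(x = "triangle class", y = "normalized Z-score") +
    ggplot2::theme_minimal()
}
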