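# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   geom_abline geom_step geom_col geom_ribbon labs facet_wrap
#'   scale_fill_viridis_c coord_equal theme_minimal annotate
NULL

#' @export
ggplot2::autoplot

#' Plot a power spectrum
#'
#' @param object A `power_spectrum` tibble.
#' @param window Optional alpha window to shade.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, window = c(8, 12), ...) {
  p <- ggplot(object, aes(x = .data$freq, y = .data$power,
                          group = .data$channel)) +
    geom_line(alpha = 0.6) +
    labs(x = "frequency (Hz)", y = expression(power ~ (mu * V^2 / Hz))) +
    theme_minimal()
  if (!is.null(window)) {
    p <- p + annotate("rect", xmin = window[1], xmax = window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "blue")
  }
  p
}

#' Plot a motor map
#'
#' Tile map of per-site mean MEP amplitude on the stimulation lattice.
#'
#' @param object A `map_grid`.
#' @param normalize Show amplitudes as percent of the maximum site.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.map_grid <- function(object, normalize = TRUE, ...) {
  m <- if (normalize) normalize_map(object) else object
  ggplot(m, aes(x = .data$col, y = .data$row, fill = .data$amplitude)) +
    geom_tile() +
    scale_fill_viridis_c(name = if (normalize) "% max MEP" else "MEP (mV)") +
    coord_equal() +
    labs(x = "grid column (cm)", y = "grid row (cm)") +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.2f (95%% CI %.2f-%.2f), %s",
                      object$auc, object$ci_low, object$ci_high, object$band)
    ) +
    theme_minimal()
}

#' Plot fitted growth-mixture trajectories
#'
#' Mean class trajectories over the fitted timepoint grid.
#'
#' @param object A `gmm_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.gmm_fit <- function(object, ...) {
  grid <- expand_grid(class = object$coefficients$class, t = object$t) |>
    left_join(object$coefficients, by = "class") |>
    mutate(score = .data$intercept + .data$slope * .data$t +
             .data$quadratic * .data$t^2)
  ggplot(grid, aes(x = .data$t, y = .data$score, colour = .data$class)) +
    geom_line(linewidth = 1) +
    labs(x = "day", y = "pain score (chewing + yawning, 0-20)",
         colour = "class") +
    theme_minimal()
}

#' Plot internal cross-validation performance by family
#'
#' @param object A `cv_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- object$summary |>
    select("family", "cv_auc", "validation_auc") |>
    pivot_longer(-"family", names_to = "stage", values_to = "auc")
  ggplot(long, aes(x = .data$family, y = .data$auc, fill = .data$stage)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "AUC") +
    theme_minimal()
}
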