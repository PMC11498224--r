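#' Plot a tau-profile
#'
#' @param object A `mf_tau_profile` from [mf_effective_number()].
#' @param ... Unused.
#' @return A ggplot: multifunctionality value against the
#'   distinctiveness threshold tau, with the AUC in the subtitle.
#' @export
autoplot.mf_tau_profile <- function(object, ...) {
  df <- tibble(tau = object$taus, value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = expression(tau), y = "multifunctionality",
      title = sprintf("Tau profile (q = %g, K = %d)", object$q, object$k),
      subtitle = sprintf("effective number (AUC) = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot transformation effects
#'
#' Effect panels in the style of a win/lose display: one facet per
#' dimension, proportional deviation from the beech baseline with its
#' bootstrap CI per forest-type transformation.
#'
#' @param object A `mf_transformation` from [transformation_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mf_transformation <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$estimate, y = .data$forest_type,
      colour = .data$label)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)
    ) +
    ggplot2::facet_wrap(~dimension, nrow = 1) +
    ggplot2::scale_colour_manual(
      values = c(win = "#1b7837", lose = "#b2182b", neutral = "grey40")
    ) +
    ggplot2::labs(
      x = "proportional deviation from pure beech", y = NULL,
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot threshold-approach curves
#'
#' Number of indicators exceeding t% of their observed maximum, per plot
#' (thin lines) and, if a design is supplied, averaged per forest type
#' (thick lines).
#'
#' @param x A `mf_threshold` table from [threshold_mf()].
#' @param design Optional design/table with `plot_id` and `forest_type`
#'   to colour group means.
#' @return A ggplot.
#' @export
plot_threshold_curves <- function(x, design = NULL) {
  p <- ggplot2::ggplot(x,
    ggplot2::aes(x = .data$threshold, y = .data$count,
      group = .data$plot_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey40") +
    ggplot2::labs(
      x = "threshold (% of observed maximum)",
      y = "number of functions above threshold"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(design)) {
    means <- x %>%
      left_join(
        dplyr::select(as_tibble(design), "plot_id", "forest_type"),
        by = "plot_id"
      ) %>%
      group_by(.data$forest_type, .data$threshold) %>%
      summarise(count = mean(.data$count), .groups = "drop")
    p <- p + ggplot2::geom_line(
      data = means,
      ggplot2::aes(group = .data$forest_type, colour = .data$forest_type),
      linewidth = 1
    )
  }
  p
}
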