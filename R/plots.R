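## ggplot2 figures for each result type. Figures the source tables also
## serve (Sankey-style flows, heatmaps) are emitted as tile/bar charts
## of the same tabular content.

#' Forest-style plot of paired diagnostic metrics
#'
#' @param object Output of [compare_modalities()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_modality_comparison <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object,
      metric = .data$metric, modality = .data$modality_a,
      estimate = .data$estimate_a, conf.low = .data$conf.low_a,
      conf.high = .data$conf.high_a
    ),
    dplyr::transmute(object,
      metric = .data$metric, modality = .data$modality_b,
      estimate = .data$estimate_b, conf.low = .data$conf.low_b,
      conf.high = .data$conf.high_b
    )
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$estimate, y = .data$metric,
      colour = .data$modality
    )
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "estimate (95% CI)", y = NULL,
      title = "Paired diagnostic performance"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.confusion_counts <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$call, y = .data$truth, fill = .data$n)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decision_impact <- function(object, ...) {
  df <- object$dose_transitions
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$from, DOSE_LEVELS),
      y = factor(.data$to, DOSE_LEVELS), fill = .data$n
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::facet_grid(node_pathology ~ oncologist_id) +
    ggplot2::labs(
      x = "dose before review", y = "dose after review",
      title = "Dose-category transitions per oncologist"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tornado_result <- function(object, ...) {
  df <- dplyr::mutate(object,
    parameter = factor(.data$parameter, rev(.data$parameter))
  )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$icer_low, xend = .data$icer_high,
      yend = .data$parameter
    ), linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(
      xintercept = object$icer_base[1],
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "ICER (US$/QALY)", y = NULL,
      title = "One-way sensitivity of the ICER"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.psa_result <- function(object, type = c("ce_plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "ce_plane") {
    ggplot2::ggplot(
      object$results,
      ggplot2::aes(x = .data$incremental_qaly, y = .data$incremental_cost)
    ) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::geom_vline(xintercept = 0) +
      ggplot2::labs(
        x = "incremental QALYs (PET/CT - MRI)",
        y = "incremental cost (US$)",
        title = "Cost-effectiveness plane"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(
      object$ceac,
      ggplot2::aes(x = .data$wtp, y = .data$prob_pet_cost_effective)
    ) +
      ggplot2::geom_line() +
      ggplot2::scale_y_continuous(limits = c(0, 1)) +
      ggplot2::labs(
        x = "willingness to pay (US$/QALY)",
        y = "P(PET/CT-first cost-effective)",
        title = "Cost-effectiveness acceptability curve"
      ) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
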