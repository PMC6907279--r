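#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a relative-approval-year performance curve
#'
#' Points per integer offset between drug approval year and network year,
#' with the centered 5-year rolling average drawn as a line; negative
#' offsets are training-era indications, positive offsets future ones.
#'
#' @param object A [relative_year_curve()] result.
#' @param metric `"auroc"` or `"auprc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot relative_year_curve
#' @export
autoplot.relative_year_curve <- function(object, metric = c("auroc", "auprc"), ...) {
  metric <- match.arg(metric)
  smooth_col <- paste0(metric, "_smooth")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data[[metric]], size = .data$n_pos), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[smooth_col]]), colour = "#2166ac", linewidth = 1) +
    ggplot2::scale_size_continuous(name = "positives") +
    ggplot2::labs(
      x = "approval year - network year",
      y = toupper(metric),
      title = "Performance by relative approval year"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-year time-split performance
#'
#' @param object A [timesplit_run()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot timesplit_result
#' @export
autoplot.timesplit_result <- function(object, ...) {
  m <- tidyr::pivot_longer(
    object$metrics[, c("network_year", "auroc", "auprc")],
    c("auroc", "auprc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(m, ggplot2::aes(.data$network_year, .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "network year", y = "metric on future indications",
      title = "Prospective performance by network year"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a perturbation suite
#'
#' Mean change in AUROC per condition with 95% confidence intervals over
#' replicates.
#'
#' @param object A [run_perturbation_suite()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perturbation_result
#' @export
autoplot.perturbation_result <- function(object, ...) {
  s <- summarize_perturbations(object)
  ggplot2::ggplot(s, ggplot2::aes(
    x = factor(.data$condition), y = .data$mean_delta_auroc,
    colour = .data$metaedge, group = .data$metaedge
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(
      x = if (object$plan$mode == "dropout") "dropout rate (%)" else "donor network year",
      y = expression(Delta * " AUROC vs baseline"),
      title = paste("Edge", object$plan$mode, "analysis")
    ) +
    ggplot2::theme_minimal()
}
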