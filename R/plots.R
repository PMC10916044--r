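# ggplot2 views of the main result types.

#' Plot sensitivity and precision distributions of a row-linear fit
#'
#' Density of per-site platform sensitivities (slopes against the
#' consensus mean) and precisions (residual scatter; smaller is
#' superior), one colour per platform.
#'
#' @param object a `rowlinear_fit` tibble from [rowlinear_fit()].
#' @param which `"sensitivity"` or `"precision"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rowlinear_fit <- function(object, which = c("sensitivity",
                                                     "precision"), ...) {
  which <- match.arg(which)
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[which]],
                                       colour = .data$platform)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = if (which == "sensitivity") 1 else 0,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = which, y = "density",
                  title = sprintf("Row-linear %s by platform", which)) +
    ggplot2::theme_minimal()
}

#' Scatterplot of on-target versus best off-target RMSE
#'
#' One point per evaluated probe; points below the identity line have
#' stronger agreement with an off-target CpG's WGBS methylation than
#' with their intended target.
#'
#' @param evidence tibble of [crosshyb_wgbs_evidence()] rows (one per
#'   probe), e.g. built with `purrr::map` + `bind_rows`.
#' @return a ggplot object.
#' @export
plot_crosshyb_evidence <- function(evidence) {
  ev <- filter(evidence, .data$flag %in% c("Y", "N"))
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$rmse_on_target,
                                   y = .data$best_off_rmse,
                                   colour = .data$flag)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(Y = "firebrick",
                                            N = "steelblue")) +
    ggplot2::labs(x = "RMSE vs on-target WGBS",
                  y = "RMSE vs best off-target WGBS",
                  colour = "off-target\nevidence") +
    ggplot2::theme_minimal()
}

#' Barplot of replicate-verdict labels
#'
#' @param verdicts tibble of [evaluate_replicate_set()] rows.
#' @return a ggplot object.
#' @export
plot_replicate_verdicts <- function(verdicts) {
  counts <- dplyr::count(filter(verdicts, !is.na(.data$label)),
                         .data$label)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "probes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Relative log methylation (RLM) box plot
#'
#' Per-sample distributions of deviations from the per-site median
#' M-value; widening boxes indicate reduced data quality.
#'
#' @param deviations tibble from [rlm_deviations()].
#' @return a ggplot object.
#' @export
plot_rlm <- function(deviations) {
  ggplot2::ggplot(deviations, ggplot2::aes(x = .data$sample,
                                           y = .data$deviation)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.3, fill = "grey90") +
    ggplot2::labs(x = NULL, y = "M-value deviation from site median") +
    ggplot2::theme_minimal()
}
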