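#' Plot carcinogenic-effect estimates
#'
#' Forest-style display of per-gene effect estimates with confidence
#' intervals on a log scale; infinite or zero estimates are flagged in the
#' axis label via the `note` column.
#'
#' @param effects A tibble from [estimate_matched()],
#'   [estimate_length_benchmark()], or a row-bound combination.
#' @return A ggplot object.
#' @export
plot_effects <- function(effects) {
  d <- effects |>
    filter(is.finite(.data$w_hat), .data$w_hat > 0) |>
    mutate(gene = stats::reorder(.data$gene, .data$w_hat))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$w_hat, y = .data$gene)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = pmax(.data$ci_low, .Machine$double.xmin),
                   xmax = .data$ci_high),
      height = 0.2, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "carcinogenic effect ŵ", y = NULL,
                  title = unique(d$method)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bp_age_profile <- function(object, ...) {
  d <- object$density |>
    tidyr::pivot_longer(c("dens_z", "dens_neutral"),
                        names_to = "mutation", values_to = "density") |>
    mutate(mutation = dplyr::recode(.data$mutation,
                                    dens_z = "mutation z",
                                    dens_neutral = "neutral")) |>
    mutate(density = .data$density / sum(.data$density),
           .by = "mutation")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$density,
                                  colour = .data$mutation)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "patient age (years)", y = "normalised cancer age density",
      title = sprintf("s = %g, w = %g (mean-age shift %+.1f y)",
                      object$s, object$w, object$mean_age_shift)) +
    ggplot2::theme_minimal()
}

#' Plot permutation-test age biases
#'
#' Age difference versus synonymous mutations per gene against the
#' permutation quantile; genes below the q-value threshold are highlighted.
#'
#' @param results A [permutation_test()] tibble.
#' @param q_cut Significance threshold on the q-value.
#' @return A ggplot object.
#' @export
plot_age_bias <- function(results, q_cut = 0.05) {
  d <- filter(results, !is.na(.data$delta_age)) |>
    mutate(significant = !is.na(.data$q_value) & .data$q_value < q_cut)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_age,
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "age difference vs synonymous (years)",
                  y = "-log10 p (permutation)") +
    ggplot2::theme_minimal()
}

#' Plot multi-hit cancer summaries
#'
#' Scatter of driver count and mean log carcinogenic effect against age at
#' transformation for sampled cancers.
#'
#' @param cancers A tibble from [sample_cancers()] or
#'   [cancer_summaries()]`$cancers`.
#' @return A ggplot object.
#' @export
plot_multihit <- function(cancers) {
  d <- cancers |>
    tidyr::pivot_longer(c("n_drivers", "mean_log_effect"),
                        names_to = "stat", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_cancer, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         na.rm = TRUE) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "age at transformation (years)", y = NULL) +
    ggplot2::theme_minimal()
}
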