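#' Kaplan-Meier plot for a stratified cohort
#'
#' Step survival curves per stratum with censoring ticks.
#'
#' @param split A `stratified_cohort` from [percentile_split()].
#' @param clinical Clinical tibble with `sample`, `os_months`, `event`.
#' @param feature_name Axis label for the stratifying feature.
#' @return A ggplot object.
#' @export
plot_km <- function(split, clinical, feature_name = "total curvature") {
  joined <- left_join(as_tibble(split), clinical, by = "sample")
  curves <- bind_rows(lapply(base::split(joined, joined$group), function(gr) {
    km <- km_estimator(gr)
    bind_rows(tibble(time = 0, survival = 1, n_censor = 0L), km[, c("time", "survival", "n_censor")]) |>
      mutate(group = gr$group[1L])
  }))
  lr <- logrank_test(joined)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(curves, .data$n_censor > 0),
                        shape = 3, size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "months", y = "survival probability",
      colour = paste(feature_name, "group"),
      title = sprintf("Kaplan-Meier by %s (log-rank p = %.2g)",
                      feature_name, lr$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Curvature profile plots
#'
#' Distribution of per-edge Ollivier-Ricci curvature and per-gene scalar
#' curvature for one sample.
#'
#' @param object A `curvature_profile`.
#' @param ... Unused.
#' @return A ggplot object (edge curvature histogram).
#' @export
autoplot.curvature_profile <- function(object, ...) {
  ggplot2::ggplot(object$edges, ggplot2::aes(x = .data$kappa)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey30") +
    ggplot2::labs(
      x = "edge Ollivier-Ricci curvature", y = "edges",
      title = sprintf("Sample %s: total curvature %.4g",
                      object$sample, object$total)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a feature association
#'
#' @param data Tibble with the two feature columns.
#' @param x,y Column names.
#' @return A ggplot object with the least-squares line and the Pearson r / p
#'   annotation.
#' @export
plot_association <- function(data, x, y) {
  fa <- feature_association(data, x, y)
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fa$slope, intercept = fa$intercept,
                         colour = "firebrick") +
    ggplot2::labs(title = sprintf("r = %.3f, p = %.3g", fa$r, fa$p_value)) +
    ggplot2::theme_minimal()
}
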