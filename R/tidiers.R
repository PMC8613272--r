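#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(group = x$groups, n = x$n, observed = x$observed,
         expected = x$expected)
}

#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n = sum(x$n), n_events = sum(x$observed))
}

#' @export
tidy.feature_association <- function(x, ...) {
  tibble(term = c("(Intercept)", x$x),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.feature_association <- function(x, ...) {
  tibble(r = x$r, r_squared = x$r^2, p_value = x$p_value, n = x$n)
}

#' @export
glance.maxstat_cutpoint <- function(x, ...) {
  tibble(cutpoint = x$cutpoint, statistic = x$statistic,
         p_naive = x$p_naive, n_candidates = x$n_candidates)
}

#' @export
tidy.curvature_profile <- function(x, ...) {
  mutate(x$nodes, sample = x$sample)[, c("sample", "gene", "pi", "kappa")]
}

#' @export
glance.curvature_profile <- function(x, ...) {
  tibble(sample = x$sample, n_genes = nrow(x$nodes), n_edges = nrow(x$edges),
         total_kappa = x$total,
         mean_edge_kappa = mean(x$edges$kappa),
         min_edge_kappa = min(x$edges$kappa),
         max_edge_kappa = max(x$edges$kappa))
}

#' @export
tidy.transport_plan <- function(x, ...) x$plan

#' @export
glance.transport_plan <- function(x, ...) {
  tibble(cost = x$cost, n_moves = nrow(x$plan))
}
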