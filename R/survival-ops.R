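#' Stratify samples at a percentile of a scalar feature
#'
#' Splits a cohort into low and high groups at the `q`-quantile of a scalar
#' feature (total network curvature, TMB, FGA, LST, ...). The cutoff uses
#' the linear-interpolation quantile convention (type 7 by default);
#' membership rule: value `<=` cutoff goes to `low`, else `high`. With 45
#' distinct values and `q = 0.25` this yields groups of 12 and 33.
#'
#' @param values Tibble with columns `sample`, `value` (any second numeric
#'   column name is accepted), or a named numeric vector.
#' @param q Quantile in (0, 1), default 0.25.
#' @param type Quantile algorithm passed to [stats::quantile()], default 7.
#' @param quiet Suppress the group-size message (default `FALSE`).
#' @return A `stratified_cohort`: tibble (`sample`, `value`, `group`) with
#'   attributes `cutoff`, `q` and `quantile_type` recording the convention.
#' @export
percentile_split <- function(values, q = 0.25, type = 7, quiet = FALSE) {
  if (is.data.frame(values)) {
    stopifnot("sample" %in% names(values), ncol(values) >= 2L)
    value_col <- setdiff(names(values), "sample")[1L]
    v <- setNames(values[[value_col]], values$sample)
  } else {
    v <- values
  }
  if (length(v) < 4L) abort("at least 4 samples are required for a split")
  if (any(!is.finite(v))) abort("non-finite feature values")
  if (length(unique(v)) == 1L) abort("degenerate split: all values identical")
  cutoff <- unname(quantile(v, probs = q, type = type))
  out <- tibble(
    sample = names(v),
    value = unname(v),
    group = factor(ifelse(v <= cutoff, "low", "high"), levels = c("low", "high"))
  )
  if (!quiet)
    inform(sprintf("percentile split at q = %g (cutoff %.6g): %d low, %d high",
                   q, cutoff, sum(out$group == "low"), sum(out$group == "high")))
  structure(out, cutoff = cutoff, q = q, quantile_type = type,
            class = c("stratified_cohort", class(out)))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function with right censoring
#' (`event = FALSE` means censored at `os_months`). A thin tidy wrapper
#' around [survival::survfit()].
#'
#' @param records Tibble with columns `os_months`, `event` (and anything
#'   else, ignored).
#' @return Tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_estimator <- function(records) {
  stopifnot(all(c("os_months", "event") %in% names(records)), nrow(records) >= 1L)
  if (any(records$os_months < 0)) abort("negative survival times")
  fit <- survival::survfit(
    survival::Surv(os_months, event) ~ 1,
    data = data.frame(os_months = records$os_months,
                      event = as.logical(records$event))
  )
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank test on 1 degree of freedom comparing the survival of
#' two groups.
#'
#' @param records_a Either the first group's records (tibble with
#'   `os_months`, `event`), or a combined tibble carrying a `group` column
#'   when `records_b` is `NULL`.
#' @param records_b Optional second group's records.
#' @return A `logrank_test` object with elements `statistic` (chi-square),
#'   `df`, `p_value`, `n` and per-group observed/expected counts; see
#'   [tidy()] and [glance()] methods.
#' @export
logrank_test <- function(records_a, records_b = NULL) {
  if (is.null(records_b)) {
    stopifnot("group" %in% names(records_a))
    dat <- data.frame(os_months = records_a$os_months,
                      event = as.logical(records_a$event),
                      group = as.factor(records_a$group))
  } else {
    dat <- data.frame(
      os_months = c(records_a$os_months, records_b$os_months),
      event = as.logical(c(records_a$event, records_b$event)),
      group = factor(rep(c("a", "b"), c(nrow(records_a), nrow(records_b))))
    )
  }
  if (nlevels(droplevels(dat$group)) != 2L) abort("exactly two non-empty groups are required")
  if (sum(dat$event) == 0L) abort("no events observed in either group")
  sd <- survival::survdiff(survival::Surv(os_months, event) ~ group, data = dat)
  stat <- unname(sd$chisq)
  structure(
    list(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
         n = unname(sd$n), observed = unname(sd$obs), expected = unname(sd$exp),
         groups = levels(droplevels(dat$group))),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.5g (n = %s)\n",
              x$statistic, x$df, x$p_value, paste(x$n, collapse = " vs ")))
  invisible(x)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans candidate cutpoints of a scalar feature within a quantile range and
#' returns the cutpoint maximising the two-group log-rank statistic
#' (membership rule value `<=` cutpoint, as in [percentile_split()]). Ties
#' are broken by the smallest cutpoint. The reported p-value is the naive
#' log-rank p at the selected cutpoint and is NOT corrected for the
#' selection over many candidate splits; treat it as exploratory.
#'
#' @param values Tibble (`sample`, `value`) or named numeric vector.
#' @param records Clinical tibble with `sample`, `os_months`, `event`.
#' @param search_range Quantile range searched, default `c(0.1, 0.9)`.
#' @return A `maxstat_cutpoint` object: list with `cutpoint`, `statistic`,
#'   `p_naive`, `n_candidates`, `search_range`.
#' @export
maxstat_cutpoint <- function(values, records, search_range = c(0.1, 0.9)) {
  if (is.data.frame(values)) {
    value_col <- setdiff(names(values), "sample")[1L]
    v <- setNames(values[[value_col]], values$sample)
  } else {
    v <- values
  }
  stopifnot(all(c("sample", "os_months", "event") %in% names(records)))
  v <- v[names(v) %in% records$sample]
  if (length(v) < 10L) abort("at least 10 samples are required for cutpoint selection")
  rec <- records[match(names(v), records$sample), ]
  lo <- quantile(v, search_range[1L], type = 7)
  hi <- quantile(v, search_range[2L], type = 7)
  cand <- sort(unique(v[v >= lo & v <= hi]))
  cand <- cand[cand < max(v)] # both groups must be non-empty
  if (length(cand) == 0L) abort("no valid cutpoint in the search range")

  stats <- vapply(cand, function(cp) {
    grp <- v <= cp
    if (sum(rec$event[grp]) + sum(rec$event[!grp]) == 0L) return(NA_real_)
    sd <- survival::survdiff(
      survival::Surv(os_months, event) ~ g,
      data = data.frame(os_months = rec$os_months, event = as.logical(rec$event),
                        g = grp)
    )
    unname(sd$chisq)
  }, 0)
  if (all(is.na(stats))) abort("no events: cannot select a cutpoint")
  best <- which(stats == max(stats, na.rm = TRUE))[1L] # smallest cutpoint on ties
  structure(
    list(cutpoint = unname(cand[best]), statistic = unname(stats[best]),
         p_naive = pchisq(stats[best], 1L, lower.tail = FALSE),
         n_candidates = length(cand), search_range = search_range),
    class = "maxstat_cutpoint"
  )
}

#' @export
print.maxstat_cutpoint <- function(x, ...) {
  cat(sprintf(paste0(
    "Maximally selected log-rank cutpoint: %.6g (chisq = %.4g over %d candidates)\n",
    "Naive p = %.4g -- exploratory; not corrected for cutpoint selection\n"),
    x$cutpoint, x$statistic, x$n_candidates, x$p_naive))
  invisible(x)
}

#' Association between two scalar sample features
#'
#' Ordinary least squares of `y` on `x` plus the Pearson correlation with its
#' two-sided t-test p-value — used to relate total network curvature to
#' comparator genomic features.
#'
#' @param data Tibble containing the two feature columns.
#' @param x,y Column names (strings) of the predictor and response.
#' @return A `feature_association` object with `r`, `p_value`, `slope`,
#'   `intercept`, `n`; see [tidy()] and [glance()] methods.
#' @export
feature_association <- function(data, x, y) {
  xv <- data[[x]]
  yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3L) abort("at least 3 paired finite values are required")
  if (var(xv) == 0 || var(yv) == 0) abort("zero variance in x or y")
  fit <- lm(yv ~ xv)
  ct <- cor.test(xv, yv, method = "pearson")
  structure(
    list(x = x, y = y, r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         n = length(xv)),
    class = "feature_association"
  )
}

#' @export
print.feature_association <- function(x, ...) {
  cat(sprintf("Association %s ~ %s: r = %.4f, p = %.4g, slope = %.4g, intercept = %.4g (n = %d)\n",
              x$y, x$x, x$r, x$p_value, x$slope, x$intercept, x$n))
  invisible(x)
}
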