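test_that("percentile split follows the interpolated quantile convention", {
  v <- stats::setNames(1:8, sprintf("p%d", 1:8))
  sp <- percentile_split(v, q = 0.25, quiet = TRUE)
  expect_equal(attr(sp, "cutoff"), 2.75)
  expect_setequal(sp$sample[sp$group == "low"], c("p1", "p2"))
  expect_equal(sum(sp$group == "high"), 6L)
})

test_that("45 distinct values split 12 low vs 33 high at the 25th percentile", {
  set.seed(42)
  v <- stats::setNames(rnorm(45), sprintf("s%02d", 1:45))
  sp <- percentile_split(v, quiet = TRUE)
  expect_equal(sum(sp$group == "low"), 12L)
  expect_equal(sum(sp$group == "high"), 33L)
})

test_that("split size is monotone in q and degenerate input errors", {
  set.seed(7)
  v <- stats::setNames(runif(30), sprintf("s%02d", 1:30))
  sizes <- vapply(c(0.1, 0.25, 0.5, 0.75),
                  function(q) sum(percentile_split(v, q, quiet = TRUE)$group == "low"),
                  0L)
  expect_true(all(diff(sizes) >= 0))
  # q = 0: only the minimum lands in the low group
  sp0 <- percentile_split(v, q = 0, quiet = TRUE)
  expect_equal(sp0$sample[sp0$group == "low"], names(v)[which.min(v)])
  expect_error(percentile_split(stats::setNames(rep(1, 5), letters[1:5]),
                                quiet = TRUE), "degenerate")
  expect_error(percentile_split(v[1:3], quiet = TRUE), "at least 4")
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  # n = 4, all events at distinct times: survival drops by 1/4 each time
  rec <- tibble::tibble(os_months = c(1, 2, 3, 4), event = TRUE)
  km <- km_estimator(rec)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))

  # all censored: flat at 1
  rec2 <- tibble::tibble(os_months = c(1, 2, 3), event = FALSE)
  expect_true(all(km_estimator(rec2)$survival == 1))

  # censoring between events changes the risk set
  rec3 <- tibble::tibble(os_months = c(1, 2, 3), event = c(TRUE, FALSE, TRUE))
  km3 <- km_estimator(rec3)
  hand <- km_bruteforce(rec3$os_months, rec3$event)
  expect_equal(km3$survival[km3$n_event > 0], hand$survival)
  expect_equal(hand$survival, c(2 / 3, 0)) # (1 - 1/3), then (1 - 1/1)

  expect_error(km_estimator(tibble::tibble(os_months = -1, event = TRUE)),
               "negative")
})

test_that("KM output is a proper non-increasing survival curve", {
  set.seed(11)
  rec <- tibble::tibble(os_months = rexp(40, 0.1),
                        event = runif(40) < 0.7)
  km <- km_estimator(rec)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  hand <- km_bruteforce(rec$os_months, rec$event)
  expect_equal(km$survival[km$n_event > 0], hand$survival, tolerance = 1e-12)
})

test_that("log-rank test: identical groups give statistic 0 and p 1", {
  rec <- tibble::tibble(os_months = c(1, 2, 3, 4, 5), event = TRUE)
  lr <- logrank_test(rec, rec)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank is symmetric in group order and validates inputs", {
  set.seed(13)
  a <- tibble::tibble(os_months = rexp(25, 0.1), event = runif(25) < 0.8)
  b <- tibble::tibble(os_months = rexp(30, 0.25), event = runif(30) < 0.8)
  l1 <- logrank_test(a, b)
  l2 <- logrank_test(b, a)
  expect_equal(l1$statistic, l2$statistic, tolerance = 1e-12)
  expect_equal(l1$p_value, l2$p_value, tolerance = 1e-12)

  none <- tibble::tibble(os_months = c(1, 2), event = FALSE)
  expect_error(logrank_test(none, none), "no events")

  g <- glance(l1)
  expect_equal(g$p_value, l1$p_value)
  expect_equal(g$n, 55)
})

test_that("grouped-table interface matches the two-table interface", {
  set.seed(17)
  dat <- sim_two_group_surv(20, 25, hr = 2, cens_rate = 0.05)
  l1 <- logrank_test(dat)
  l2 <- logrank_test(dat[dat$group == "a", ], dat[dat$group == "b", ])
  expect_equal(l1$statistic, l2$statistic, tolerance = 1e-12)
})

test_that("maxstat cutpoint lands between well-separated survival clusters", {
  set.seed(19)
  n <- 40
  value <- c(runif(n / 2, 0, 1), runif(n / 2, 9, 10))
  rec <- tibble::tibble(
    sample = sprintf("s%02d", 1:n),
    os_months = c(rexp(n / 2, 1), rexp(n / 2, 0.05)),
    event = TRUE
  )
  v <- stats::setNames(value, rec$sample)
  ms <- maxstat_cutpoint(v, rec)
  # a perfect split keeps every low-cluster value at or below the cutpoint
  # (ties break to the smallest such cutpoint) and excludes the high cluster
  expect_gte(ms$cutpoint, max(value[1:(n / 2)]) - 1e-12)
  expect_lt(ms$cutpoint, 9)
  expect_gt(ms$statistic, 0)
})

test_that("maxstat stays within the search range under a monotone hazard", {
  set.seed(23)
  n <- 60
  value <- runif(n)
  rec <- tibble::tibble(sample = sprintf("s%02d", 1:n),
                        os_months = rexp(n, exp(2 * value) / 10),
                        event = TRUE)
  v <- stats::setNames(value, rec$sample)
  ms <- maxstat_cutpoint(v, rec)
  expect_gte(ms$cutpoint, unname(quantile(value, 0.1)))
  expect_lte(ms$cutpoint, unname(quantile(value, 0.9)))
  expect_gt(ms$statistic, 0)
  expect_error(maxstat_cutpoint(v[1:5], rec[1:5, ]), "at least 10")
})

test_that("feature association recovers an exact linear relationship", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  fa <- feature_association(d, "x", "y")
  expect_equal(fa$r, 1, tolerance = 1e-12)
  expect_equal(fa$slope, 2, tolerance = 1e-12)
  expect_equal(fa$intercept, 1, tolerance = 1e-12)
  expect_error(feature_association(tibble::tibble(x = rep(1, 5), y = 1:5),
                                   "x", "y"), "zero variance")
  expect_error(feature_association(d[1:2, ], "x", "y"), "at least 3")
})

test_that("independent features show weak association", {
  set.seed(29)
  d <- tibble::tibble(x = rnorm(100), y = rnorm(100))
  fa <- feature_association(d, "x", "y")
  expect_lt(abs(fa$r), 0.3)
  g <- glance(fa)
  expect_equal(g$r, fa$r)
})
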