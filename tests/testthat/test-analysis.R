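test_that("histograms conserve counts and handle degenerate input", {
  set.seed(2)
  w <- rlnorm(10000, 0, 1)
  h <- weight_histogram(w)
  expect_identical(nrow(h), 80L)
  expect_identical(sum(h$count), 10000L)
  expect_true(all(diff(h$bin_lo) > 0))
  expect_true(all(h$bin_hi > h$bin_lo))

  h1 <- weight_histogram(rep(2.5, 100))
  expect_identical(sum(h1$count == 100L), 1L)  # single occupied bin
  expect_identical(sum(h1$count), 100L)

  expect_error(weight_histogram(c(1, -1)), "positive")
  expect_error(weight_histogram(numeric(0)), "no weights")

  hd <- change_histogram(c(rnorm(500, 0, 0.1), NA))
  expect_identical(sum(hd$count), 500L)
})

test_that("histogram scope separates silent and active synapses", {
  st <- tibble::tibble(w = c(rep(0.05, 30), rlnorm(70, 0, 0.5)),
                       active = c(rep(FALSE, 30), rep(TRUE, 70)))
  h_all <- weight_histogram(st, "all")
  h_act <- weight_histogram(st, "active")
  expect_identical(sum(h_all$count), 100L)
  expect_identical(sum(h_act$count), 70L)
  expect_true(min(h_act$bin_lo) > 0.05)
})

test_that("fit_lognormal recovers known parameters", {
  # parameter recovery at the scale of a full ensemble histogram
  set.seed(31)
  w <- rlnorm(10000, meanlog = 0.0131, sdlog = 0.9341)
  f <- fit_lognormal(w)
  expect_equal(unname(f$estimate["meanlog"]), 0.0131,
               tolerance = 3 * 0.9341 / sqrt(10000) / 0.0131)
  expect_lt(abs(f$estimate["meanlog"] - 0.0131),
            3 * f$std_error["meanlog"])
  expect_lt(abs(f$estimate["sdlog"] - 0.9341), 3 * f$std_error["sdlog"])
  fh <- fit_lognormal(w, method = "histogram")
  expect_equal(unname(fh$estimate["sdlog"]),
               unname(f$estimate["sdlog"]), tolerance = 0.05)
  expect_error(fit_lognormal(c(w[1:5], -1)), "10 weights")
  expect_error(fit_lognormal(rep(1, 100)), "spread")
})

test_that("fit_normal recovers known parameters, with and without a peak", {
  set.seed(32)
  x <- rnorm(20000, 0, 0.07)
  f <- fit_normal(x)
  expect_lt(abs(f$estimate["mean"]), 3 * f$std_error["mean"])
  expect_lt(abs(f$estimate["sd"] - 0.07), 3 * f$std_error["sd"])

  # contaminate with a sharp spike at zero; peak-excluding fits recover
  spiked <- c(x, rnorm(4000, 0, 0.004))
  raw <- fit_normal(spiked)
  expect_gt(abs(raw$estimate["sd"] - 0.07), 0.004)  # spike biases raw sd
  fh <- fit_normal(spiked, exclude_peak = TRUE, epsilon = 0.02)
  expect_lt(abs(fh$estimate["sd"] - 0.07), 0.005)
  ft <- fit_normal(spiked, exclude_peak = TRUE, epsilon = 0.02,
                   method = "truncated")
  expect_lt(abs(ft$estimate["sd"] - 0.07), 0.005)
})

test_that("percent daily change is the mean relative increment", {
  tab <- tibble::tibble(w_pre = c(1, 2, 4), dw = c(0.165, -0.2, NA))
  expect_equal(percent_daily_change(tab), 100 * mean(c(0.165, 0.1)))
  expect_equal(percent_daily_change(
    tibble::tibble(w_pre = 1, dw = rep(0, 10))), 0)
})

test_that("the increment profile bins by start weight and flattens", {
  set.seed(33)
  w_pre <- rlnorm(20000, 0, 1)
  # increment magnitude proportional to w * volatility: relative change
  # must fall with w
  p <- spine_params()
  dw <- w_pre * volatility(w_pre, p) * rnorm(20000, 0, 0.057)
  prof <- delta_vs_w_profile(tibble::tibble(w_pre = w_pre, dw = dw))
  expect_identical(sum(prof$n), 20000L)
  big <- prof$n >= 200
  rel <- prof$mean_rel_change[big]
  expect_gt(rel[1], rel[sum(big)])  # decreasing overall
  flat <- delta_vs_w_profile(tibble::tibble(w_pre = w_pre, dw = 0.5))
  expect_true(all(flat$mean_dw == 0.5))
  expect_true(all(flat$mean_abs_dw == 0.5))
})

test_that("pearson_r implements the product-moment formula", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:3, 3:1), -1)
  # hand-computed: sum of cross-deviations 11, variances 5 and 26
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 5, 9)), 11 / sqrt(130))
  set.seed(4)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(pearson_r(x, y), cor(x, y))
  expect_equal(pearson_r(2 * x + 3, 0.5 * y - 1), pearson_r(x, y))
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("decay-constant fitting recovers tau and rejects degenerate input", {
  days <- seq(0, 1500, by = 10)
  f <- fit_decay_time_constant(tibble::tibble(day = days,
                                              r = exp(-days / 500)))
  expect_equal(unname(f$estimate["tau"]), 500, tolerance = 1e-4)
  set.seed(5)
  noisy <- exp(-days / 500) + rnorm(length(days), 0, 0.01)
  fn <- fit_decay_time_constant(days, noisy)
  expect_equal(unname(fn$estimate["tau"]), 500, tolerance = 0.05)
  fo <- fit_decay_time_constant(
    tibble::tibble(day = days, r = 0.2 + 0.8 * exp(-days / 300)),
    with_offset = TRUE)
  expect_equal(unname(fo$estimate["tau"]), 300, tolerance = 1e-3)
  expect_equal(unname(fo$estimate["offset"]), 0.2, tolerance = 1e-3)
  expect_error(fit_decay_time_constant(days, rep(1, length(days))),
               "constant")
  expect_error(fit_decay_time_constant(1:5, exp(-(1:5))), "10 samples")
})

test_that("the empirical reference model is piecewise and continuous", {
  expect_equal(yasumatsu_c1(0.6), 0)
  expect_equal(yasumatsu_c1(0.1), -0.006)
  expect_equal(yasumatsu_c1(0.5), 0.12 * 0.5 - 0.06)  # = 0 at boundary
  expect_equal(yasumatsu_c1(0.25), -0.16 * 0.25 + 0.01)  # first branch
  # continuity across both branch points
  eps <- 1e-9
  expect_equal(yasumatsu_c1(0.25 - eps), yasumatsu_c1(0.25 + eps),
               tolerance = 1e-6)
  expect_equal(yasumatsu_c1(0.5 - eps), yasumatsu_c1(0.5 + eps),
               tolerance = 1e-6)
  expect_error(yasumatsu_c1(-0.1), "nonnegative")
})

test_that("tidy and glance expose fit results in broom shape", {
  set.seed(6)
  f <- fit_lognormal(rlnorm(100, 0, 1))
  td <- tidy(f)
  expect_identical(td$term, c("meanlog", "sdlog"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  g <- glance(f)
  expect_identical(nrow(g), 1L)
  expect_identical(g$family, "lognormal")
})
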