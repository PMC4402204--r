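# Protocol behaviour is exercised here at reduced scale (tens of clusters,
# short burn-ins); the full-scale quantitative reproductions live in
# test-acceptance.R.

test_that("protocols are deterministic given (params, seed)", {
  p <- spine_params()
  a <- steady_state_protocol(p, seed = 9, n_clusters = 30L, burn_in = 500L)
  b <- steady_state_protocol(p, seed = 9, n_clusters = 30L, burn_in = 500L)
  expect_identical(a$summaries, b$summaries)
  expect_identical(a$data$day_record, b$data$day_record)
  c <- steady_state_protocol(p, seed = 10, n_clusters = 30L,
                             burn_in = 500L)
  expect_false(identical(a$summaries$mean_w, c$summaries$mean_w))
})

test_that("steady-state protocol produces coherent summaries", {
  p <- spine_params()
  pr <- steady_state_protocol(p, seed = 9, n_clusters = 50L,
                              burn_in = 1500L)
  s <- pr$summaries
  expect_identical(s$n_synapses, 500L)
  expect_equal(s$n_active + s$silent_pct * 5, 500)
  expect_gt(s$pct_daily_change, 0)
  expect_gt(s$sdlog_active, 0)
  expect_identical(sum(pr$data$histogram_all$count), 500L)
  expect_identical(sum(pr$data$histogram_active$count), s$n_active)
  # histogram has no mass below the silent weight
  expect_gte(min(pr$data$histogram_all$bin_lo), p$w_sil * 0.999)
  g <- glance(pr)
  expect_identical(g$protocol, "steady_state")
})

test_that("perturbation protocol reduces to identity at scale 1", {
  p <- spine_params()
  pr <- perturbation_protocol(p, seed = 11, ltp_scale = 1,
                              n_clusters = 40L, burn_in = 800L)
  # identical seeds and identical parameters: the two runs coincide
  expect_equal(pr$summaries$pct_decrease_mean_w, 0)
  expect_identical(pr$data$baseline_state, pr$data$perturbed_state)
  expect_error(perturbation_protocol(p, ltp_scale = 0), "ltp_scale")
  expect_error(perturbation_protocol(p, ltp_scale = 1.2), "ltp_scale")
})

test_that("perturbation scales the right amplitude fields per variant", {
  p <- spine_params()
  ps <- scale_ltp(p, 0.95)
  expect_equal(ps$x1, 0.144 * 0.95)
  expect_equal(ps$x2, 0.18 * 0.95)
  pf <- scale_ltp(spine_params(variant = "fixed_ltp"), 0.98)
  expect_equal(pf$a1_fixed, 0.16 * 0.98)
  expect_equal(pf$sd1_fixed, 0.16 * 0.98 / 4)
})

test_that("memory imprint resets exactly and tracks the subset", {
  p <- spine_params()
  st <- small_steady_state(40L, 1500L)
  mi <- memory_imprint_protocol(p, seed = 13, burn_in = 0L, t_reset = 0L,
                                follow_days = 70L, sample_every = 7L,
                                state = st)
  tr <- mi$data$trace
  expect_identical(tr$day[1], 0L)
  expect_equal(tr$mean_w[1], 5.0)  # forced assignment, exact
  expect_equal(tr$sd_w[1], 0)
  expect_identical(nrow(tr), 11L)
  expect_true(all(is.finite(tr$mean_w)))
  expect_error(
    memory_imprint_protocol(p, w_high = 0.05, state = st, burn_in = 0L),
    "t_wk")
})

test_that("an imprint with equal high/low weights keeps the two subsets
           exchangeable", {
  p <- spine_params()
  st <- small_steady_state(60L, 1500L)
  mi <- memory_imprint_protocol(p, seed = 14, burn_in = 0L, t_reset = 0L,
                                w_high = 1.0, w_low = 1.0,
                                follow_days = 300L, sample_every = 300L,
                                state = st)
  fin <- mi$data$final_state
  lo <- fin$w[fin$synapse <= 5]
  hi <- fin$w[fin$synapse > 5]
  # same reset, same dynamics: subset means differ only by sampling noise
  expect_lt(abs(mean(lo) - mean(hi)) /
              sqrt(var(lo) / length(lo) + var(hi) / length(hi)), 4)
})

test_that("decorrelation series starts at exactly 1 and loses memory", {
  p <- spine_params()
  st <- small_steady_state(60L, 1500L)
  dc <- decorrelation_protocol(p, seed = 15, burn_in = 0L, horizon = 400L,
                               sample_every = 20L, state = st)
  ser <- dc$data$series
  expect_identical(ser$r[ser$day == 0], 1)
  expect_true(all(ser$r <= 1 & ser$r >= -1))
  expect_gt(dc$summaries$tau, 0)
  # a shuffled comparison pattern carries no correlation
  set.seed(1)
  shuffled <- sample(st$w)
  expect_lt(abs(pearson_r(st$w, shuffled)), 4 / sqrt(length(shuffled)))
})

test_that("cluster stability protocol reports the N_st band occupancy", {
  p <- spine_params()
  st <- small_steady_state(40L, 1500L)
  cs <- cluster_stability_protocol(p, seed = 16, burn_in = 0L,
                                   horizon = 200L, state = st)
  expect_identical(nrow(cs$data$n_strong), 200L * 40L)
  expect_true(cs$summaries$frac_in_range >= 0 &&
                cs$summaries$frac_in_range <= 1)
  expect_true(all(cs$data$n_strong$n_strong <= p$n_cl))
})
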