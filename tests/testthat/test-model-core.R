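p_std <- spine_params()

test_that("volatility matches its closed form and is strictly decreasing", {
  expect_equal(volatility(0, p_std), 4.0)
  expect_equal(volatility(0.4, p_std), (4.0 + 0.2) / 2)  # midpoint at w_med
  expect_equal(volatility(1.0, p_std), 4.0 - 3.8 * (1 / 1.4),
               tolerance = 1e-12)
  grid <- volatility(seq(0, 100, by = 0.25), p_std)
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid > p_std$v_lo & grid <= p_std$v_hi))
  expect_error(volatility(-0.1, p_std), "nonnegative")
})

test_that("mean LTP amplitude interpolates x2 -> x1 and respects variants", {
  expect_equal(ltp_mean_amplitude(0, p_std), 0.18)
  expect_equal(ltp_mean_amplitude(10, p_std), 0.144)
  expect_equal(ltp_mean_amplitude(5, p_std), 0.162)
  a <- ltp_mean_amplitude(0:10, p_std)
  expect_true(all(diff(a) <= 0))
  expect_true(all(a >= p_std$x1 & a <= p_std$x2))
  expect_error(ltp_mean_amplitude(11, p_std), "n_cl")
  expect_error(ltp_mean_amplitude(-1, p_std), "n_cl")

  p_fix <- spine_params(variant = "fixed_ltp")
  expect_equal(ltp_mean_amplitude(0:10, p_fix), rep(0.16, 11))
})

test_that("amplitude operations follow the update equations", {
  # A_LTP = W r1 VO (1 - k_hi W / (W + w_hi)); A_LTD = W r2 VO
  vo1 <- 4.0 - 3.8 * (1 / 1.4)
  expect_equal(ltp_amplitude(1.0, 0.18, p_std),
               0.18 * vo1 * (1 - 0.05 * (1 / 21)), tolerance = 1e-12)
  expect_equal(ltd_amplitude(1.0, 0.16, p_std), 0.16 * vo1,
               tolerance = 1e-12)
  expect_equal(ltp_amplitude(0, 0.5, p_std), 0)
  expect_equal(ltd_amplitude(0, 0.5, p_std), 0)
  expect_equal(ltp_amplitude(2, 0, p_std), 0)
  expect_equal(ltd_amplitude(2, 0, p_std), 0)
  # saturation factor tends to 1 - k_hi at large W
  w_big <- 1e8
  expect_equal(ltp_amplitude(w_big, 1, p_std) /
                 (w_big * volatility(w_big, p_std)),
               1 - p_std$k_hi, tolerance = 1e-6)
  expect_error(ltp_amplitude(-1, 0.1, p_std), "nonnegative")
  expect_error(ltd_amplitude(1, -0.1, p_std), "nonnegative")
})

test_that("increment draws have the nominal mean and are never negative", {
  set.seed(101)
  n <- 1e6
  r <- draw_increment(n, 0.16, p_std, role = "ltd")
  expect_true(all(r >= 0))
  # truncation at 4 sd is negligible: sample mean within 4 standard errors
  expect_lt(abs(mean(r) - 0.16), 4 * 0.04 / sqrt(n))
  expect_equal(sd(r), 0.04, tolerance = 0.01)

  p_exp <- spine_params(variant = "exponential_increments", lambda1 = 2,
                        lambda2 = 0.5)
  r1 <- draw_increment(n, 0.16, p_exp, role = "ltp")
  expect_lt(abs(mean(r1) - 0.5), 4 * 0.5 / sqrt(n))
  r2 <- draw_increment(1e5, 0.16, p_exp, role = "ltd")
  expect_equal(mean(r2), 2, tolerance = 0.05)
  expect_error(draw_increment(10, 0, p_std), "positive")
  expect_error(draw_increment(10, -1, p_std), "positive")
})

test_that("regeneration probability scales with the strong count", {
  expect_equal(regeneration_probability(0, p_std), 0)
  expect_equal(regeneration_probability(5, p_std), 0.05)
  expect_equal(regeneration_probability(10, p_std), 0.1)
  expect_error(regeneration_probability(11, p_std), "n_cl")
  p_nr <- spine_params(variant = "no_regeneration")
  expect_equal(regeneration_probability(0:10, p_nr), rep(0, 11))
})

test_that("a fully silent cluster is a fixed point of the day update", {
  cl <- tibble::tibble(w = rep(p_std$w_sil, 10), active = FALSE)
  set.seed(1)
  out <- step_cluster(cl, p_std)
  expect_equal(out$w, cl$w)
  expect_equal(out$active, cl$active)
  expect_true(all(is.na(out$dw)))
})

test_that("zero increments leave active weights unchanged", {
  cl <- tibble::tibble(w = c(5, rep(p_std$w_sil, 9)),
                       active = c(TRUE, rep(FALSE, 9)))
  out <- step_cluster(cl, p_std, r1 = rep(0, 10), r2 = rep(0, 10),
                      u = rep(0.99, 10))
  expect_equal(out$w[1], 5)
  expect_true(out$active[1])
  expect_equal(out$dw[1], 0)
})

test_that("silencing resets a synapse to the silent basal weight", {
  cl <- tibble::tibble(w = c(0.1, 5, rep(p_std$w_sil, 8)),
                       active = c(TRUE, TRUE, rep(FALSE, 8)))
  # large LTD increment drives synapse 1 below t_wk
  out <- step_cluster(cl, p_std, r1 = rep(0, 10), r2 = c(1, 0, rep(0, 8)),
                      u = rep(0.99, 10))
  expect_false(out$active[1])
  expect_equal(out$w[1], p_std$w_sil)
  # dw records the pre-silencing increment, not the reset
  expect_equal(out$dw[1], -ltd_amplitude(0.1, 1, p_std))
})

test_that("regeneration requires a strong chain neighbour and resets W", {
  # synapse 2 strong; synapses 1 and 3 silent; synapse 5 silent with no
  # strong neighbour
  cl <- tibble::tibble(
    w = c(p_std$w_sil, 5, p_std$w_sil, 0.2, p_std$w_sil,
          rep(0.2, 5)),
    active = c(FALSE, TRUE, FALSE, TRUE, FALSE, rep(TRUE, 5)))
  out <- step_cluster(cl, p_std, r1 = rep(0, 10), r2 = rep(0, 10),
                      u = rep(0, 10))  # u = 0 < P_ACT: always regenerate
  expect_true(out$active[1])
  expect_equal(out$w[1], p_std$w_reset)
  expect_true(out$active[3])
  expect_false(out$active[5])  # gated out: neighbours 4 and 6 not strong
  expect_equal(out$w[5], p_std$w_sil)
})

test_that("a synapse silenced today cannot regenerate today", {
  cl <- tibble::tibble(w = c(0.1, 5, rep(0.2, 8)),
                       active = rep(TRUE, 10))
  out <- step_cluster(cl, p_std, r1 = rep(0, 10), r2 = c(1, rep(0, 9)),
                      u = rep(0, 10))
  expect_false(out$active[1])
  expect_equal(out$w[1], p_std$w_sil)
})

test_that("the day update preserves cluster size and weight positivity", {
  p <- p_std
  for (seed in 1:20) {
    cl <- random_cluster(p, seed)
    out <- step_cluster(cl, p)
    expect_identical(nrow(out), p$n_cl)
    expect_true(all(out$w > 0))
    expect_equal(sum(out$active) + sum(!out$active), p$n_cl)
    expect_true(all(out$w[!out$active] == p$w_sil))
    expect_true(all(out$w[out$active] >= p$t_wk))
  }
})
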