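#' Weight-dependent volatility factor
#'
#' Multiplicative factor applied to both the LTP and LTD amplitudes,
#' `v_hi - (v_hi - v_lo) * W / (W + w_med)`. It decreases from `v_hi` at
#' `W = 0` towards `v_lo` for `W >> w_med`, so small synapses fluctuate
#' relatively more; at `W = w_med` it is midway between the bounds.
#'
#' @param w Synaptic weight(s), nonnegative.
#' @param params A [spine_params()] object.
#' @return Numeric vector of volatility factors in `(v_lo, v_hi]`.
#' @examples
#' volatility(0.4, spine_params())  # (4 + 0.2) / 2
#' @export
volatility <- function(w, params = spine_params()) {
  stopifnot(is.numeric(w))
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  params$v_hi - (params$v_hi - params$v_lo) * w / (w + params$w_med)
}

#' Mean LTP amplitude under cluster resource competition
#'
#' The mean daily LTP increment `a1` decreases linearly with the number of
#' strong synapses in the cluster, from `x2` when none are strong to `x1`
#' when all `n_cl` are: maintaining strong synapses consumes shared
#' resources (mRNAs/proteins) that would otherwise support growth. Under
#' the `fixed_ltp` variant the coupling is removed and `a1_fixed` is
#' returned regardless of `n_st`.
#'
#' @param n_st Number of strong synapses in the cluster, in `0:n_cl`.
#' @param params A [spine_params()] object.
#' @return Mean LTP amplitude, bounded in `[x1, x2]`.
#' @examples
#' ltp_mean_amplitude(0:10, spine_params())
#' @export
ltp_mean_amplitude <- function(n_st, params = spine_params()) {
  stopifnot(is.numeric(n_st))
  if (any(n_st < 0 | n_st > params$n_cl)) {
    stop("n_st must lie in [0, n_cl]", call. = FALSE)
  }
  if (params$variant == "fixed_ltp") {
    return(rep(params$a1_fixed, length(n_st)))
  }
  params$x2 - (params$x2 - params$x1) * n_st / params$n_cl
}

#' Draw daily increment magnitudes
#'
#' Draws the random variables `r1`/`r2` that scale the LTP and LTD
#' amplitudes. In the Gaussian variants the draw has the given mean and
#' standard deviation `mean / sd_ratio` (for the LTP increment of the
#' `fixed_ltp` variant, `sd1_fixed`), with negative draws clamped to zero.
#' Under `exponential_increments` the draw is exponential with rate
#' `lambda1` (LTP) or `lambda2` (LTD); the `mean` argument then only
#' selects the role.
#'
#' @param n Number of draws.
#' @param mean Nominal mean of the increment; must be positive.
#' @param params A [spine_params()] object.
#' @param role `"ltp"` or `"ltd"`.
#' @return Nonnegative numeric vector of length `n`.
#' @export
draw_increment <- function(n, mean, params = spine_params(),
                           role = c("ltp", "ltd")) {
  role <- match.arg(role)
  if (!is.numeric(mean) || length(mean) != 1 || mean <= 0) {
    stop("increment mean must be a positive number", call. = FALSE)
  }
  if (params$variant == "exponential_increments") {
    rate <- if (role == "ltp") params$lambda1 else params$lambda2
    return(stats::rexp(n, rate = rate))
  }
  sd <- if (role == "ltp" && params$variant == "fixed_ltp") {
    params$sd1_fixed
  } else {
    mean / params$sd_ratio
  }
  pmax(0, stats::rnorm(n, mean, sd))
}

#' LTP and LTD amplitudes
#'
#' The daily LTP amplitude is
#' `W * r1 * VO(W) * (1 - k_hi * W / (W + w_hi))`: proportional to the
#' preexisting weight, the increment draw and the volatility factor, with a
#' saturating correction that keeps weights bounded. The LTD amplitude is
#' `W * r2 * VO(W)`.
#'
#' @param w Weight(s), nonnegative.
#' @param r1,r2 Increment draw(s), nonnegative.
#' @param params A [spine_params()] object.
#' @return Nonnegative amplitude(s); zero when `w` or the draw is zero.
#' @export
ltp_amplitude <- function(w, r1, params = spine_params()) {
  stopifnot(is.numeric(w), is.numeric(r1))
  if (any(w < 0) || any(r1 < 0)) {
    stop("weights and increments must be nonnegative", call. = FALSE)
  }
  vo <- volatility(w, params)
  w * r1 * vo * (1 - params$k_hi * w / (w + params$w_hi))
}

#' @rdname ltp_amplitude
#' @export
ltd_amplitude <- function(w, r2, params = spine_params()) {
  stopifnot(is.numeric(w), is.numeric(r2))
  if (any(w < 0) || any(r2 < 0)) {
    stop("weights and increments must be nonnegative", call. = FALSE)
  }
  w * r2 * volatility(w, params)
}

#' Daily regeneration probability of a silent synapse
#'
#' `p_bas * n_st / n_cl`: regeneration is more likely in clusters with more
#' strong synapses, up to the maximal value `p_bas`. Regeneration is
#' additionally gated on chain adjacency (see [step_cluster()]). Under the
#' `no_regeneration` variant the probability is zero.
#'
#' @param n_st Number of strong synapses in the cluster, in `0:n_cl`.
#' @param params A [spine_params()] object.
#' @return Probability in `[0, p_bas]`.
#' @export
regeneration_probability <- function(n_st, params = spine_params()) {
  stopifnot(is.numeric(n_st))
  if (any(n_st < 0 | n_st > params$n_cl)) {
    stop("n_st must lie in [0, n_cl]", call. = FALSE)
  }
  if (params$variant == "no_regeneration") {
    return(rep(0, length(n_st)))
  }
  params$p_bas * n_st / params$n_cl
}

#' One simulated day for a single cluster (reference implementation)
#'
#' Pure-R, per-synapse loop implementing one synchronous daily update for a
#' cluster: snapshot of the strong-synapse count and flags at day start;
#' LTP/LTD update of every day-start-active synapse; silencing of synapses
#' whose updated weight fell below `t_wk`; adjacency-gated regeneration of
#' day-start-silent synapses. A synapse silenced today cannot regenerate
#' today. Synapses form a non-periodic chain: synapse `i` is adjacent to
#' `i - 1` and `i + 1`.
#'
#' Draws come from the current R random stream in a fixed order (synapses in
#' index order, `r1` before `r2`, then one uniform per day-start-silent
#' synapse), matching the compiled ensemble driver draw for draw, so this
#' function serves as an independent oracle for [run_days()].
#'
#' @param cluster Data frame with numeric column `w` and logical column
#'   `active`, one row per synapse; silent rows must have `w = w_sil`.
#' @param params A [spine_params()] object.
#' @param r1,r2 Optional fixed increment vectors (length `n_cl`) used in
#'   place of random draws, for deterministic testing.
#' @param u Optional fixed uniforms (length `n_cl`) for the regeneration
#'   draws.
#' @return A tibble with columns `w`, `active` and `dw` (the day's
#'   pre-silencing weight increment; `NA` for day-start-silent synapses).
#' @export
step_cluster <- function(cluster, params = spine_params(),
                         r1 = NULL, r2 = NULL, u = NULL) {
  stopifnot(is.data.frame(cluster),
            all(c("w", "active") %in% names(cluster)))
  n <- nrow(cluster)
  if (n != params$n_cl) {
    stop("cluster must have n_cl = ", params$n_cl, " synapses",
         call. = FALSE)
  }
  w <- cluster$w
  active <- cluster$active
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)

  strong <- active & w > params$t_st
  n_st <- sum(strong)
  was_silent <- !active
  a1 <- ltp_mean_amplitude(n_st, params)
  sd1 <- if (params$variant == "fixed_ltp") {
    params$sd1_fixed
  } else {
    a1 / params$sd_ratio
  }
  sd2 <- params$a2 / params$sd_ratio
  expo <- params$variant == "exponential_increments"

  dw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!active[i]) next
    if (is.null(r1)) {
      if (expo) {
        r1i <- stats::rexp(1, rate = params$lambda1)
        r2i <- stats::rexp(1, rate = params$lambda2)
      } else {
        r1i <- stats::rnorm(1, a1, sd1)
        if (r1i < 0) r1i <- 0
        r2i <- stats::rnorm(1, params$a2, sd2)
        if (r2i < 0) r2i <- 0
      }
    } else {
      r1i <- r1[i]
      r2i <- r2[i]
    }
    vo <- params$v_hi - (params$v_hi - params$v_lo) * w[i] /
      (w[i] + params$w_med)
    a_ltp <- w[i] * r1i * vo * (1 - params$k_hi * w[i] / (w[i] + params$w_hi))
    a_ltd <- w[i] * r2i * vo
    dw[i] <- a_ltp - a_ltd
    w[i] <- w[i] + dw[i]
  }

  sil <- active & w < params$t_wk
  active[sil] <- FALSE
  w[sil] <- params$w_sil

  pact <- if (params$variant == "no_regeneration") {
    0
  } else {
    params$p_bas * n_st / params$n_cl
  }
  for (i in seq_len(n)) {
    if (!was_silent[i]) next
    ui <- if (is.null(u)) stats::runif(1) else u[i]
    if (params$variant == "no_regeneration") next
    gate <- (i > 1 && strong[i - 1]) || (i < n && strong[i + 1])
    if (gate && ui < pact) {
      active[i] <- TRUE
      w[i] <- params$w_reset
    }
  }

  tibble::tibble(w = w, active = active, dw = dw)
}
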