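#' Model parameters for clustered spine-weight dynamics
#'
#' Builds the full parameter set of the daily weight-update model. The
#' defaults are the standard values used throughout: clusters of
#' `n_cl = 10` synapses, regeneration weight `w_reset = 0.4`, silent basal
#' weight `w_sil = 0.05`, silencing threshold `t_wk = 0.08`, strong-synapse
#' threshold `t_st = 0.8`, volatility bounds `v_hi = 4`, `v_lo = 0.2` with
#' half-saturation `w_med = 0.4`, mean LTP amplitude falling linearly from
#' `x2 = 0.18` (no strong synapses in the cluster) to `x1 = 0.144` (all
#' strong), mean LTD amplitude `a2 = 0.16`, LTP saturation `k_hi = 0.05`,
#' `w_hi = 20`, and maximal daily regeneration probability `p_bas = 0.1`.
#' Increment draws are Gaussian with standard deviation `mean / sd_ratio`
#' (`sd_ratio = 4`), negative draws clamped to zero.
#'
#' All weights are dimensionless (spine volume is the empirical proxy); one
#' time step corresponds to one day.
#'
#' @param n_cl Integer, synapses per cluster (chain topology).
#' @param w_reset Weight assigned on regeneration.
#' @param w_sil Basal weight of a silent synapse.
#' @param t_wk Silencing threshold: an active synapse whose updated weight
#'   falls below `t_wk` is reset to silent.
#' @param t_st Strong-synapse threshold: a synapse with `W > t_st` is strong.
#' @param v_hi,v_lo Volatility factor bounds (value at `W = 0` and the
#'   large-`W` limit).
#' @param w_med Weight at which the volatility factor is midway between
#'   `v_hi` and `v_lo`.
#' @param x1,x2 Minimum/maximum mean LTP amplitude.
#' @param a2 Mean LTD amplitude.
#' @param sd_ratio Ratio of increment mean to its standard deviation.
#' @param k_hi,w_hi LTP saturation parameters; the LTP amplitude carries a
#'   factor `1 - k_hi * W / (W + w_hi)`.
#' @param p_bas Maximal regeneration probability per day.
#' @param variant Model variant: `"standard"`; `"fixed_ltp"` (mean and sd of
#'   the LTP increment fixed at `a1_fixed`, `sd1_fixed`, no resource
#'   coupling of the LTP amplitude); `"no_regeneration"` (silent synapses
#'   never regenerate); `"exponential_increments"` (`r1`, `r2` drawn from
#'   exponential distributions with decay rate constants `lambda1`,
#'   `lambda2` instead of Gaussians).
#' @param a1_fixed,sd1_fixed Mean and sd of the LTP increment under
#'   `variant = "fixed_ltp"`.
#' @param lambda1,lambda2 Decay rate constants (density proportional to
#'   `exp(-lambda * r)`) for the exponential-increment variant; the values
#'   explored in practice lie in `[0.5, 3]`.
#'
#' @return A validated `spine_params` object (named list).
#' @examples
#' p <- spine_params()
#' volatility(c(0, 0.4, 1), p)
#' @export
spine_params <- function(n_cl = 10L, w_reset = 0.4, w_sil = 0.05,
                         t_wk = 0.08, t_st = 0.8, v_hi = 4.0, v_lo = 0.2,
                         w_med = 0.4, x1 = 0.144, x2 = 0.18, a2 = 0.16,
                         sd_ratio = 4, k_hi = 0.05, w_hi = 20.0,
                         p_bas = 0.1,
                         variant = c("standard", "fixed_ltp",
                                     "no_regeneration",
                                     "exponential_increments"),
                         a1_fixed = 0.16, sd1_fixed = 0.04,
                         lambda1 = 1.0, lambda2 = 1.0) {
  variant <- match.arg(variant)
  p <- list(n_cl = as.integer(n_cl), w_reset = w_reset, w_sil = w_sil,
            t_wk = t_wk, t_st = t_st, v_hi = v_hi, v_lo = v_lo,
            w_med = w_med, x1 = x1, x2 = x2, a2 = a2, sd_ratio = sd_ratio,
            k_hi = k_hi, w_hi = w_hi, p_bas = p_bas, variant = variant,
            a1_fixed = a1_fixed, sd1_fixed = sd1_fixed,
            lambda1 = lambda1, lambda2 = lambda2)
  validate_spine_params(p)
  structure(p, class = "spine_params")
}

validate_spine_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in setdiff(names(p), "variant")) {
    chk(num1(p[[f]]), sprintf("parameter '%s' must be a finite number", f))
  }
  chk(p$n_cl >= 2, "n_cl must be at least 2")
  chk(p$w_sil > 0 && p$w_sil < p$t_wk && p$t_wk < p$t_st,
      "thresholds must satisfy 0 < w_sil < t_wk < t_st")
  chk(p$x1 > 0 && p$x1 <= p$x2, "LTP amplitudes must satisfy 0 < x1 <= x2")
  chk(p$v_lo > 0 && p$v_lo < p$v_hi,
      "volatility bounds must satisfy 0 < v_lo < v_hi")
  chk(p$w_med > 0, "w_med must be positive")
  chk(p$w_hi > 0, "w_hi must be positive")
  chk(p$k_hi >= 0 && p$k_hi < 1, "k_hi must lie in [0, 1)")
  chk(p$p_bas >= 0 && p$p_bas <= 1, "p_bas must lie in [0, 1]")
  chk(p$sd_ratio > 0, "sd_ratio must be positive")
  chk(p$a2 > 0, "a2 must be positive")
  chk(p$w_reset > p$t_wk, "w_reset must exceed t_wk")
  chk(p$a1_fixed > 0 && p$sd1_fixed > 0,
      "a1_fixed and sd1_fixed must be positive")
  chk(p$lambda1 > 0 && p$lambda2 > 0,
      "lambda1 and lambda2 must be positive")
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a new, revalidated `spine_params` with the named fields replaced.
#'
#' @param params A [spine_params()] object.
#' @param ... Named fields to replace.
#' @return A `spine_params` object.
#' @examples
#' update_params(spine_params(), x1 = 0.144 * 0.95, x2 = 0.18 * 0.95)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "spine_params"))
  new <- list(...)
  bad <- setdiff(names(new), names(unclass(params)))
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(spine_params, utils::modifyList(unclass(params), new))
}

# Scale the mean LTP amplitude by a factor; for the fixed-amplitude variant
# the fixed mean is scaled and its sd keeps the mean/sd ratio.
scale_ltp <- function(params, factor) {
  stopifnot(factor > 0)
  if (params$variant == "fixed_ltp") {
    a1 <- params$a1_fixed * factor
    update_params(params, a1_fixed = a1, sd1_fixed = a1 / params$sd_ratio)
  } else {
    update_params(params, x1 = params$x1 * factor,
                  x2 = params$x2 * factor)
  }
}

#' @export
print.spine_params <- function(x, ...) {
  cat("<spine_params> variant:", x$variant, "\n")
  num <- unclass(x)
  num$variant <- NULL
  cat(paste0("  ", names(num), " = ", unlist(num), collapse = "\n"), "\n")
  invisible(x)
}

#' Read or write a parameter file
#'
#' Parameters are stored as a flat YAML key-value map. Omitted keys take the
#' standard defaults; unknown keys are an error.
#'
#' @param path File path.
#' @return `read_spine_params()` returns a `spine_params` object;
#'   `write_spine_params()` invisibly returns `path`.
#' @export
read_spine_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), names(formals(spine_params)))
  if (length(bad) > 0) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(spine_params, raw)
}

#' @rdname read_spine_params
#' @param params A [spine_params()] object.
#' @export
write_spine_params <- function(params, path) {
  stopifnot(inherits(params, "spine_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
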