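#' Log-binned weight histogram
#'
#' Bins weights into `n_bins` bins of equal width in natural-log units
#' spanning the observed range (the steady-state active range spans roughly
#' five natural-log units). Counts are conserved.
#'
#' @param x Ensemble state tibble (columns `w`, `active`), a `spine_run`
#'   (its final state is used), or a numeric weight vector.
#' @param scope `"all"` (silent synapses included at `w_sil`) or
#'   `"active"`.
#' @param n_bins Number of bins.
#' @return A `spine_histogram` tibble with columns `bin_lo`, `bin_hi`,
#'   `bin_mid` (geometric midpoint) and `count`.
#' @export
weight_histogram <- function(x, scope = c("all", "active"), n_bins = 80L) {
  scope <- match.arg(scope)
  w <- extract_weights(x, scope)
  if (length(w) == 0) stop("no weights in scope", call. = FALSE)
  if (any(w <= 0)) stop("weights must be positive for log binning",
                        call. = FALSE)
  h <- bin_counts(log(w), n_bins)
  out <- tibble::tibble(bin_lo = exp(h$lo), bin_hi = exp(h$hi),
                        bin_mid = exp((h$lo + h$hi) / 2), count = h$count)
  structure(out, class = c("spine_histogram", class(out)),
            scale = "log", scope = scope, n = length(w))
}

#' Linear-binned histogram of daily weight changes
#'
#' @param dw Numeric vector of daily weight increments (typically the
#'   non-`NA` `dw` column of a recorded day).
#' @param n_bins Number of bins.
#' @return A `spine_histogram` tibble (linear scale).
#' @export
change_histogram <- function(dw, n_bins = 80L) {
  dw <- dw[!is.na(dw)]
  if (length(dw) == 0) stop("no increments supplied", call. = FALSE)
  h <- bin_counts(dw, n_bins)
  out <- tibble::tibble(bin_lo = h$lo, bin_hi = h$hi,
                        bin_mid = (h$lo + h$hi) / 2, count = h$count)
  structure(out, class = c("spine_histogram", class(out)),
            scale = "linear", scope = "active", n = length(dw))
}

# Least-squares fit of a scaled normal curve to binned counts, with a free
# amplitude so excluded or non-normal mass (e.g. a spike near zero) does
# not distort the location/scale estimates. Optionally excludes bins whose
# centre lies within `exclude` of zero.
hist_curve_fit <- function(x, n_bins, mean0, sd0, n, exclude = NULL) {
  h <- bin_counts(x, n_bins)
  mid <- (h$lo + h$hi) / 2
  width <- h$hi - h$lo
  keep <- rep(TRUE, length(mid))
  if (!is.null(exclude)) keep <- abs(mid) > exclude
  if (sum(keep) < 5) stop("excluded window covers the histogram",
                          call. = FALSE)
  obj <- function(p) {
    fit <- exp(p[3]) * width[keep] * stats::dnorm(mid[keep], p[1],
                                                  exp(p[2]))
    sum((h$count[keep] - fit)^2)
  }
  opt <- stats::optim(c(mean0, log(sd0), log(n)), obj)
  list(mean = opt$par[1], sd = exp(opt$par[2]),
       amplitude = exp(opt$par[3]))
}

bin_counts <- function(x, n_bins) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    eps <- max(abs(rng[1]), 1) * 1e-6
    rng <- rng + c(-eps, eps)
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  list(lo = edges[-(n_bins + 1)], hi = edges[-1], count = counts)
}

extract_weights <- function(x, scope = "all") {
  if (inherits(x, "spine_run")) x <- x$state
  if (is.data.frame(x)) {
    if (scope == "active") {
      if (!"active" %in% names(x)) {
        stop("data frame has no 'active' column", call. = FALSE)
      }
      return(x$w[x$active])
    }
    return(x$w)
  }
  stopifnot(is.numeric(x))
  x
}

new_spine_fit <- function(family, estimate, std_error, n, method,
                          extra = list()) {
  structure(c(list(family = family, estimate = estimate,
                   std_error = std_error, n = n, method = method), extra),
            class = "spine_fit")
}

#' Fit a log-normal distribution to synaptic weights
#'
#' Default is maximum likelihood on the natural-log weights
#' (`meanlog = mean(ln W)`, `sdlog = sd(ln W)`). `method = "histogram"`
#' instead least-squares fits a scaled log-normal curve to the log-binned
#' histogram, mirroring a curve fit to a plotted histogram; the two agree
#' closely for well-behaved samples.
#'
#' @param x State tibble, `spine_run`, or positive numeric weights.
#' @param scope Which weights to fit when `x` is a state: `"active"`
#'   (default; a log-normal cannot represent the silent spike at `w_sil`)
#'   or `"all"`.
#' @param method `"mle"` or `"histogram"`.
#' @param n_bins Bins used by the histogram method.
#' @return A `spine_fit` with estimates `meanlog`, `sdlog`.
#' @export
fit_lognormal <- function(x, scope = c("active", "all"),
                          method = c("mle", "histogram"), n_bins = 80L) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  w <- extract_weights(x, scope)
  n <- length(w)
  if (n < 10) stop("need at least 10 weights", call. = FALSE)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  lw <- log(w)
  mu <- mean(lw)
  sigma <- stats::sd(lw)
  if (sigma < 1e-8) stop("weights have (near) zero spread", call. = FALSE)
  if (method == "histogram") {
    ls <- hist_curve_fit(lw, n_bins, mu, sigma, n, exclude = NULL)
    mu <- ls$mean
    sigma <- ls$sd
  }
  new_spine_fit(
    "lognormal",
    estimate = c(meanlog = mu, sdlog = sigma),
    std_error = c(meanlog = sigma / sqrt(n),
                  sdlog = sigma / sqrt(2 * (n - 1))),
    n = n, method = method
  )
}

#' Fit a normal distribution to daily weight changes
#'
#' Plain moment estimates of mean and sd, or a peak-excluding fit that
#' ignores the sharp spike of near-zero changes (contributed by the
#' smallest active synapses, whose increments are proportional to their
#' weight). With `exclude_peak = TRUE`, the default `method = "histogram"`
#' least-squares fits a scaled normal curve to the binned counts, excluding
#' bins whose centre lies within `epsilon` of zero — the direct analogue of
#' fitting a curve to a plotted histogram while ignoring the spike;
#' `method = "truncated"` instead solves for the sd of a normal
#' distribution whose `|dw - mean| > epsilon` tail second moment matches
#' the sample (more weight on the heavy tails, hence typically a somewhat
#' larger sd).
#'
#' @param dw Numeric vector of daily increments (`NA`s dropped).
#' @param exclude_peak Exclude the near-zero spike before fitting.
#' @param epsilon Half-width of the excluded window around zero.
#' @param method `"truncated"` or `"histogram"` (only used when
#'   `exclude_peak = TRUE`).
#' @param n_bins Bins for the histogram method.
#' @return A `spine_fit` with estimates `mean`, `sd`.
#' @export
fit_normal <- function(dw, exclude_peak = FALSE, epsilon = 0.02,
                       method = c("histogram", "truncated"),
                       n_bins = 80L) {
  method <- match.arg(method)
  dw <- dw[!is.na(dw)]
  n <- length(dw)
  if (n < 10) stop("need at least 10 values", call. = FALSE)
  m <- mean(dw)
  s <- stats::sd(dw)
  if (s < 1e-12) stop("values have (near) zero spread", call. = FALSE)
  used_method <- "moments"
  if (exclude_peak) {
    stopifnot(epsilon > 0)
    if (method == "truncated") {
      tail_vals <- dw[abs(dw - m) > epsilon]
      if (length(tail_vals) < 10) {
        stop("too few values outside the excluded window", call. = FALSE)
      }
      m2 <- mean((tail_vals - m)^2)
      # E[(X-m)^2 | |X-m| > eps] for X ~ N(m, s^2); Mills ratio on the
      # log scale to stay finite for eps >> s
      cond_m2 <- function(s) {
        a <- epsilon / s
        mills <- a * exp(stats::dnorm(a, log = TRUE) -
                           stats::pnorm(a, lower.tail = FALSE,
                                        log.p = TRUE))
        s^2 * (1 + mills)
      }
      lo <- epsilon / 50
      hi <- 20 * s
      s <- stats::uniroot(function(z) cond_m2(z) - m2, c(lo, hi),
                          tol = 1e-10)$root
      n <- length(tail_vals)
      used_method <- "truncated"
    } else {
      ls <- hist_curve_fit(dw, n_bins, m, s, n, exclude = epsilon)
      m <- ls$mean
      s <- ls$sd
      used_method <- "histogram"
    }
  }
  new_spine_fit(
    "normal",
    estimate = c(mean = m, sd = s),
    std_error = c(mean = s / sqrt(n), sd = s / sqrt(2 * (n - 1))),
    n = n, method = used_method
  )
}

#' Mean relative daily weight change
#'
#' `100 * mean(|dw| / w_pre)` over synapses that were active at day start,
#' the quantity used to anchor the model's time step to the ~1-day interval
#' between spine-imaging sessions.
#'
#' @param data A `spine_run` with recorded deltas, or a data frame with
#'   columns `w_pre` and `dw` (rows with `NA` `dw` are day-start-silent and
#'   are dropped).
#' @param day Which recorded day to use when `data` is a run (default:
#'   last).
#' @return Percentage (scalar).
#' @export
percent_daily_change <- function(data, day = NULL) {
  tab <- delta_table(data, day)
  100 * mean(abs(tab$dw) / tab$w_pre)
}

delta_table <- function(data, day = NULL) {
  if (inherits(data, "spine_run")) {
    if (is.null(data$weights) || !"dw" %in% names(data$weights)) {
      stop("run has no recorded deltas", call. = FALSE)
    }
    data <- data$weights
  }
  stopifnot(is.data.frame(data), all(c("w_pre", "dw") %in% names(data)))
  if (!is.null(day)) {
    data <- data[data$day == day, ]
  } else if ("day" %in% names(data)) {
    data <- data[data$day == max(data$day), ]
  }
  data <- data[!is.na(data$dw), ]
  if (nrow(data) == 0) stop("no active-synapse increments", call. = FALSE)
  if (any(data$w_pre <= 0)) stop("w_pre must be positive", call. = FALSE)
  data
}

#' Daily weight change profiled against initial weight
#'
#' Bins start-of-day weights into `n_bins` log-spaced bins and summarises
#' the day's increments per bin: signed mean and sd, and the mean magnitude
#' `|dw|`. The relative change `|dw| / w_pre` falls substantially with
#' `w_pre` — the property that makes strong synapses selectively stable.
#'
#' @inheritParams percent_daily_change
#' @param n_bins Number of log-spaced bins for `w_pre`.
#' @return A `spine_profile` tibble with per-bin columns `bin_lo`,
#'   `bin_hi`, `bin_mid`, `n`, `mean_dw`, `sd_dw`, `mean_abs_dw`,
#'   `mean_rel_change`.
#' @export
delta_vs_w_profile <- function(data, day = NULL, n_bins = 80L) {
  tab <- delta_table(data, day)
  lw <- log(tab$w_pre)
  rng <- range(lw)
  if (rng[1] == rng[2]) rng <- rng + c(-1e-6, 1e-6)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(lw, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > n_bins] <- n_bins
  out <- tibble::tibble(bin = idx, dw = tab$dw, w_pre = tab$w_pre) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_dw = mean(.data$dw),
      sd_dw = stats::sd(.data$dw),
      mean_abs_dw = mean(abs(.data$dw)),
      mean_rel_change = mean(abs(.data$dw) / .data$w_pre),
      .groups = "drop"
    )
  out$bin_lo <- exp(edges[out$bin])
  out$bin_hi <- exp(edges[out$bin + 1])
  out$bin_mid <- exp((edges[out$bin] + edges[out$bin + 1]) / 2)
  out <- out[, c("bin_lo", "bin_hi", "bin_mid", "n", "mean_dw", "sd_dw",
                 "mean_abs_dw", "mean_rel_change")]
  structure(out, class = c("spine_profile", class(out)))
}

#' Pearson product-moment correlation
#'
#' Direct implementation of the standard formula
#' `sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`,
#' used for the weight decorrelation analysis.
#'
#' @param x,y Equal-length numeric vectors with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) stop("zero variance in x or y", call. = FALSE)
  sum(dx * dy) / sqrt(vx * vy)
}

#' Fit an exponential decay time constant to a correlation series
#'
#' Nonlinear least squares of `R(t) = exp(-t / tau)` (or, with
#' `with_offset = TRUE`, `R(t) = c + (1 - c) exp(-t / tau)`) to a series of
#' correlation coefficients against lag.
#'
#' @param data Data frame with columns `day` and `r`, or a numeric vector
#'   of days (then `r` must be supplied).
#' @param r Correlation values when `data` is a vector of days.
#' @param with_offset Fit the additive-offset form.
#' @return A `spine_fit` with estimate `tau` (days) and, for the offset
#'   form, `offset`.
#' @export
fit_decay_time_constant <- function(data, r = NULL, with_offset = FALSE) {
  if (is.data.frame(data)) {
    stopifnot(all(c("day", "r") %in% names(data)))
    day <- data$day
    rv <- data$r
  } else {
    day <- data
    rv <- r
  }
  stopifnot(is.numeric(day), is.numeric(rv), length(day) == length(rv))
  if (length(day) < 10) stop("need at least 10 samples", call. = FALSE)
  if (stats::sd(rv) < 1e-10) {
    stop("correlation series is constant; no decay to fit", call. = FALSE)
  }
  ok <- day > 0 & rv > 0 & rv < 1
  tau0 <- if (any(ok)) stats::median(-day[ok] / log(rv[ok])) else max(day) / 3
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(day) / 3
  df <- data.frame(day = day, r = rv)
  if (with_offset) {
    fit <- minpack.lm::nlsLM(r ~ c0 + (1 - c0) * exp(-day / tau),
                             data = df,
                             start = list(c0 = max(0, min(rv)), tau = tau0))
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    new_spine_fit("exponential_decay",
                  estimate = c(tau = unname(est["tau"]),
                               offset = unname(est["c0"])),
                  std_error = c(tau = unname(se["tau"]),
                                offset = unname(se["c0"])),
                  n = length(day), method = "nls")
  } else {
    fit <- minpack.lm::nlsLM(r ~ exp(-day / tau), data = df,
                             start = list(tau = tau0))
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    new_spine_fit("exponential_decay",
                  estimate = c(tau = unname(est["tau"])),
                  std_error = c(tau = unname(se["tau"])),
                  n = length(day), method = "nls")
  }
}

#' Empirical daily spine-volume change (piecewise-linear reference model)
#'
#' The piecewise-linear relationship between a dendritic spine's volume `V`
#' (micrometres cubed) and its expected daily change, estimated from
#' longitudinal imaging of hippocampal spines under control conditions:
#' `dV = -0.16 V + 0.01` for `V <= 0.25`, `dV = 0.12 V - 0.06` for
#' `0.25 < V <= 0.5`, and `dV = 0` above. It is the empirical anchor used
#' to argue that one model time step corresponds to roughly one day; it is
#' provided for documentation and comparison and plays no role in the
#' simulation itself.
#'
#' @param v Spine volume(s), nonnegative, in micrometres cubed.
#' @return Expected daily volume change(s).
#' @examples
#' yasumatsu_c1(c(0.1, 0.25, 0.4, 0.6))
#' @export
yasumatsu_c1 <- function(v) {
  stopifnot(is.numeric(v))
  if (any(v < 0)) stop("volumes must be nonnegative", call. = FALSE)
  ifelse(v <= 0.25, -0.16 * v + 0.01,
         ifelse(v <= 0.5, 0.12 * v - 0.06, 0))
}

#' @export
print.spine_fit <- function(x, ...) {
  cat("<spine_fit> family:", x$family, " method:", x$method,
      " n:", x$n, "\n")
  print(round(x$estimate, 6))
  invisible(x)
}

#' @export
tidy.spine_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(x$std_error[names(x$estimate)]))
}

#' @export
glance.spine_fit <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$estimate))
  out$family <- x$family
  out$method <- x$method
  out$n <- x$n
  out
}
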