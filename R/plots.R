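#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a weight or increment histogram
#'
#' Log-binned weight histograms are drawn against `ln W`; increment
#' histograms on a linear axis. An optional fitted curve (a
#' [fit_lognormal()] or [fit_normal()] result) is overlaid scaled to the
#' counts.
#'
#' @param object A `spine_histogram`.
#' @param fit Optional `spine_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spine_histogram <- function(object, fit = NULL, ...) {
  log_scale <- attr(object, "scale") == "log"
  n <- attr(object, "n")
  df <- tibble::as_tibble(object)
  if (log_scale) {
    df$x <- log(df$bin_mid)
    df$width <- log(df$bin_hi) - log(df$bin_lo)
    xlab <- "ln W"
  } else {
    df$x <- df$bin_mid
    df$width <- df$bin_hi - df$bin_lo
    xlab <- expression(Delta * W)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$count)) +
    ggplot2::geom_col(width = df$width[1], fill = "grey30") +
    ggplot2::labs(x = xlab, y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(df$x), max(df$x), length.out = 200)
    dens <- if (fit$family == "lognormal") {
      stats::dnorm(xs, fit$estimate["meanlog"], fit$estimate["sdlog"])
    } else {
      stats::dnorm(xs, fit$estimate["mean"], fit$estimate["sd"])
    }
    curve <- tibble::tibble(x = xs, y = n * df$width[1] * dens)
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "red", linewidth = 0.8)
  }
  p
}

#' Plot a daily-change-versus-weight profile
#'
#' Mean daily increment per log-spaced weight bin with a plus/minus one
#' standard deviation band.
#'
#' @param object A `spine_profile` from [delta_vs_w_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spine_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_dw - .data$sd_dw,
      ymax = .data$mean_dw + .data$sd_dw), fill = "red", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_dw)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "W at day start",
                  y = expression(Delta * W ~ "(mean" %+-% "sd)")) +
    ggplot2::theme_minimal()
}

#' Plot a protocol result
#'
#' Draws the protocol's canonical figure: steady-state weight histogram
#' with its log-normal fit, imprinted-subset decay trace, correlation
#' decay with its exponential fit, strong-synapse-count traces, or
#' baseline-versus-perturbed mean weights.
#'
#' @param object A `spine_protocol`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spine_protocol <- function(object, ...) {
  d <- object$data
  switch(object$name,
    steady_state = autoplot(d$histogram_all, fit = d$lognormal_fit),
    memory_imprint = {
      steady <- object$summaries$steady_mean_w
      ggplot2::ggplot(d$trace, ggplot2::aes(x = .data$day)) +
        ggplot2::geom_ribbon(ggplot2::aes(
          ymin = .data$mean_w - .data$sd_w,
          ymax = .data$mean_w + .data$sd_w), fill = "red", alpha = 0.2) +
        ggplot2::geom_line(ggplot2::aes(y = .data$mean_w)) +
        ggplot2::geom_hline(yintercept = steady, linetype = 2) +
        ggplot2::labs(x = "days after imprint",
                      y = "imprinted-subset weight") +
        ggplot2::theme_minimal()
    },
    decorrelation = {
      tau <- object$summaries$tau
      curve <- tibble::tibble(
        day = seq(0, max(d$series$day), length.out = 200))
      curve$r <- exp(-curve$day / tau)
      ggplot2::ggplot(d$series, ggplot2::aes(x = .data$day, y = .data$r)) +
        ggplot2::geom_point(size = 0.6) +
        ggplot2::geom_line(data = curve, colour = "red") +
        ggplot2::labs(x = "days since reference", y = "Pearson R") +
        ggplot2::theme_minimal()
    },
    cluster_stability = {
      nst <- d$n_strong
      show <- nst[nst$cluster %in% unique(nst$cluster)[1:4], ]
      ggplot2::ggplot(show, ggplot2::aes(x = .data$day,
                                         y = .data$n_strong,
                                         colour = factor(.data$cluster))) +
        ggplot2::geom_step(show.legend = FALSE) +
        ggplot2::labs(x = "day", y = "strong synapses per cluster") +
        ggplot2::theme_minimal()
    },
    perturbation = {
      s <- object$summaries
      df <- tibble::tibble(
        run = factor(c("baseline", "perturbed"),
                     levels = c("baseline", "perturbed")),
        mean_w = c(s$mean_w_baseline, s$mean_w_perturbed))
      ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$mean_w)) +
        ggplot2::geom_col(width = 0.5, fill = "grey30") +
        ggplot2::labs(x = NULL, y = "mean W (all synapses)") +
        ggplot2::theme_minimal()
    },
    stop("no plot defined for protocol '", object$name, "'",
         call. = FALSE)
  )
}
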