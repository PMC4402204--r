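#' Initialise an ensemble of independent clusters
#'
#' Creates the tidy ensemble state: one row per synapse, with clusters
#' numbered `1:n_clusters` and synapses `1:n_cl` along each chain. All
#' synapses start active at `w_init`; the long burn-in used by every
#' protocol erases the initial condition (the weight pattern decorrelates
#' with a time constant of a few hundred days).
#'
#' @param n_clusters Number of independent clusters (1,000 in the standard
#'   protocols).
#' @param params A [spine_params()] object.
#' @param w_init Initial weight of every synapse.
#' @return A tibble with columns `cluster`, `synapse`, `w`, `active`.
#' @examples
#' state <- init_ensemble(5)
#' nrow(state)  # 5 clusters x 10 synapses
#' @export
init_ensemble <- function(n_clusters = 1000L, params = spine_params(),
                          w_init = 1.0) {
  if (!is.numeric(n_clusters) || length(n_clusters) != 1 || n_clusters < 1) {
    stop("n_clusters must be a positive integer", call. = FALSE)
  }
  n_clusters <- as.integer(n_clusters)
  stopifnot(is.numeric(w_init), w_init > 0)
  tibble::tibble(
    cluster = rep(seq_len(n_clusters), each = params$n_cl),
    synapse = rep(seq_len(params$n_cl), times = n_clusters),
    w = w_init,
    active = TRUE
  )
}

# Validate a tidy state and return the n_cl x n_clusters weight/active
# matrices expected by the compiled driver.
state_matrices <- function(state, params) {
  stopifnot(is.data.frame(state),
            all(c("cluster", "synapse", "w", "active") %in% names(state)))
  n_cl <- params$n_cl
  if (nrow(state) %% n_cl != 0) {
    stop("state size is not a multiple of n_cl", call. = FALSE)
  }
  ord <- order(state$cluster, state$synapse)
  state <- state[ord, ]
  n_clusters <- nrow(state) / n_cl
  if (!all(state$synapse == rep(seq_len(n_cl), times = n_clusters))) {
    stop("each cluster must contain synapses 1:n_cl exactly once",
         call. = FALSE)
  }
  if (any(state$w < 0)) stop("weights must be nonnegative", call. = FALSE)
  list(w = matrix(state$w, nrow = n_cl),
       active = matrix(state$active, nrow = n_cl),
       n_clusters = as.integer(n_clusters))
}

#' Advance an ensemble through simulated days
#'
#' Runs every cluster forward `n_days` days through the compiled daily
#' update (see [step_cluster()] for the within-day semantics, which the
#' compiled driver reproduces draw for draw). State can optionally be
#' recorded every `record_every` days.
#'
#' @param state Ensemble tibble from [init_ensemble()] or a previous run's
#'   `$state`.
#' @param params A [spine_params()] object.
#' @param n_days Number of days to simulate (at least 1).
#' @param seed Optional integer seed (`set.seed()` is called if supplied;
#'   otherwise the current RNG stream is used).
#' @param record_every Record state every this many days; 0 disables
#'   recording (burn-in mode).
#' @param record Character vector choosing what to record on recorded days:
#'   any of `"weights"` (end-of-day weight and status per synapse),
#'   `"deltas"` (start-of-day weight `w_pre` and the day's pre-silencing
#'   increment `dw`, `NA` for day-start-silent synapses), `"n_strong"`
#'   (start-of-day strong-synapse count per cluster).
#' @return A `spine_run` object: list with `state` (final ensemble tibble),
#'   `summary` (per recorded day: `n_active`, `mean_w`, `mean_w_active`),
#'   and, when requested, `weights` and `n_strong` long tibbles.
#' @examples
#' run <- run_days(init_ensemble(10), spine_params(), 50, seed = 1,
#'                 record_every = 10)
#' run$summary
#' @export
run_days <- function(state, params = spine_params(), n_days,
                     seed = NULL, record_every = 0L,
                     record = c("weights", "deltas")) {
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 1) {
    stop("n_days must be at least 1", call. = FALSE)
  }
  record <- match.arg(record, c("weights", "deltas", "n_strong"),
                      several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  m <- state_matrices(state, params)
  rec_on <- record_every > 0
  rec_w <- rec_on && "weights" %in% record
  rec_d <- rec_on && "deltas" %in% record
  rec_n <- rec_on && "n_strong" %in% record

  out <- run_engine(m$w, m$active, unclass(params), as.integer(n_days),
                    as.integer(record_every), rec_w, rec_d, rec_n)

  n_cl <- params$n_cl
  n_clusters <- m$n_clusters
  nsyn <- n_cl * n_clusters
  final <- tibble::tibble(
    cluster = rep(seq_len(n_clusters), each = n_cl),
    synapse = rep(seq_len(n_cl), times = n_clusters),
    w = as.vector(out$w),
    active = as.vector(out$active)
  )
  days <- out$rec_days
  summary <- tibble::tibble(
    day = days,
    n_active = out$n_active,
    mean_w = out$mean_w,
    mean_w_active = out$mean_w_active
  )

  weights <- NULL
  if (rec_w || rec_d) {
    weights <- tibble::tibble(
      day = rep(days, each = nsyn),
      cluster = rep(rep(seq_len(n_clusters), each = n_cl), times = length(days)),
      synapse = rep(rep(seq_len(n_cl), times = n_clusters), times = length(days))
    )
    if (rec_w) {
      weights$w <- as.vector(t(out$w_rec))
      weights$active <- as.vector(t(out$active_rec))
    }
    if (rec_d) {
      weights$w_pre <- as.vector(t(out$w_pre_rec))
      weights$dw <- as.vector(t(out$dw_rec))
    }
  }
  n_strong <- NULL
  if (rec_n) {
    n_strong <- tibble::tibble(
      day = rep(days, each = n_clusters),
      cluster = rep(seq_len(n_clusters), times = length(days)),
      n_strong = as.vector(t(out$n_strong_rec))
    )
  }

  structure(list(state = final, summary = summary, weights = weights,
                 n_strong = n_strong, n_days = as.integer(n_days),
                 params = params),
            class = "spine_run")
}

#' @export
print.spine_run <- function(x, ...) {
  n <- nrow(x$state)
  cat("<spine_run> ", x$n_days, " day(s), ", n, " synapses (",
      n / x$params$n_cl, " clusters of ", x$params$n_cl, ")\n", sep = "")
  cat("  active at end:", sum(x$state$active), "/", n, "\n")
  if (nrow(x$summary) > 0) {
    cat("  recorded days:", length(x$summary$day), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.spine_run <- function(x, ...) x$summary

#' @export
glance.spine_run <- function(x, ...) {
  s <- x$state
  tibble::tibble(
    n_days = x$n_days,
    n_synapses = nrow(s),
    n_active = sum(s$active),
    silent_fraction = mean(!s$active),
    mean_w = mean(s$w),
    mean_w_active = mean(s$w[s$active])
  )
}
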