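# The quantitative-reproduction suite is meant to report every deviation:
# raise the progress reporter's failure cap where the option is honoured.
options(testthat.progress.max_fails = 100L)

# Shared fixtures. Heavy steady-state ensembles are computed once per test
# session and cached; all sizes are chosen so the whole suite runs on one
# CPU in well under the time a coffee takes.

.spinedyn_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .spinedyn_cache)) {
    assign(key, force(expr), envir = .spinedyn_cache)
  }
  get(key, envir = .spinedyn_cache)
}

# Standard-parameter ensemble equilibrated past burn-in (stationarity of the
# summaries from 10,000 days on is checked in test-ensemble.R).
standard_steady_state <- function() {
  cached("steady_std", {
    p <- spine_params()
    set.seed(424242)
    run_days(init_ensemble(1000L, p), p, 10000L)$state
  })
}

# One analysed steady-state day (weights, deltas) of the standard model.
standard_steady_day <- function() {
  cached("steady_day", {
    p <- spine_params()
    set.seed(515151)
    run_days(standard_steady_state(), p, 1L, record_every = 1L,
             record = c("weights", "deltas"))
  })
}

# A small equilibrated ensemble for cheap qualitative checks.
small_steady_state <- function(n_clusters = 50L, burn_in = 2000L,
                               params = spine_params(), seed = 777L) {
  key <- paste("small", n_clusters, burn_in, params$variant, seed,
               sep = "_")
  cached(key, {
    set.seed(seed)
    run_days(init_ensemble(n_clusters, params), params, burn_in)$state
  })
}

random_cluster <- function(params = spine_params(), seed = 1) {
  set.seed(seed)
  n <- params$n_cl
  w <- stats::rlnorm(n, 0, 1)
  active <- w > params$t_wk
  w[!active] <- params$w_sil
  tibble::tibble(w = w, active = active)
}
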