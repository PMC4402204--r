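#' Read a run configuration file
#'
#' A run configuration is a YAML file with top-level keys `seed`
#' (mandatory), `protocol` (one of `steady_state`, `perturbation`,
#' `memory_imprint`, `decorrelation`, `cluster_stability`), `n_clusters`,
#' `burn_in`, `record_every`, `output_dir`, `params` (a map of
#' [spine_params()] fields; omitted fields take the standard defaults) and
#' `options` (protocol-specific arguments such as `ltp_scale`, `t_reset`,
#' `w_high`, `w_low`, `horizon`, `sample_every`, `with_offset`). Unknown
#' keys anywhere are an error naming the offending key.
#'
#' @param path Path to the YAML file.
#' @return A validated `spine_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "protocol", "n_clusters", "burn_in", "record_every",
             "output_dir", "params", "options")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$seed)) stop("configuration must set 'seed'", call. = FALSE)
  protocols <- c("steady_state", "perturbation", "memory_imprint",
                 "decorrelation", "cluster_stability")
  protocol <- raw$protocol %||% "steady_state"
  if (!protocol %in% protocols) {
    stop("unknown protocol '", protocol, "'", call. = FALSE)
  }
  params <- if (is.null(raw$params)) {
    spine_params()
  } else {
    bad <- setdiff(names(raw$params), names(formals(spine_params)))
    if (length(bad) > 0) {
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    do.call(spine_params, raw$params)
  }
  burn_in <- raw$burn_in %||% 50000L
  if (burn_in < 0) stop("burn_in must be nonnegative", call. = FALSE)
  structure(list(
    seed = as.integer(raw$seed),
    protocol = protocol,
    n_clusters = as.integer(raw$n_clusters %||% 1000L),
    burn_in = as.integer(burn_in),
    record_every = as.integer(raw$record_every %||% 1L),
    output_dir = raw$output_dir %||% ".",
    params = params,
    options = raw$options %||% list()
  ), class = "spine_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the protocol described by a configuration
#'
#' @param config A `spine_config` from [read_run_config()].
#' @return The protocol's `spine_protocol` result.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "spine_config"))
  fn <- switch(config$protocol,
               steady_state = steady_state_protocol,
               perturbation = perturbation_protocol,
               memory_imprint = memory_imprint_protocol,
               decorrelation = decorrelation_protocol,
               cluster_stability = cluster_stability_protocol)
  args <- c(list(params = config$params, seed = config$seed,
                 n_clusters = config$n_clusters,
                 burn_in = config$burn_in),
            config$options)
  do.call(fn, args)
}

#' Write a protocol result to an output directory
#'
#' Writes a YAML manifest (protocol name, seed, full parameter set and
#' scalar summaries — sufficient to re-run the experiment exactly) plus
#' tab-separated artifact tables for each tabular component of the result.
#'
#' @param result A `spine_protocol`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of files written.
#' @export
write_protocol <- function(result, dir) {
  stopifnot(inherits(result, "spine_protocol"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (nm in names(result$data)) {
    obj <- result$data[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(as.data.frame(obj), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files[nm] <- f
    } else if (inherits(obj, "spine_fit")) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(as.data.frame(tidy(obj)), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files[nm] <- f
    }
  }
  manifest <- list(
    protocol = result$name,
    seed = result$seed,
    package_version = as.character(utils::packageVersion("spinedyn")),
    params = unclass(result$params),
    summaries = lapply(result$summaries, function(s) {
      if (is.logical(s)) s else as.numeric(s)
    }),
    artifacts = as.list(files)
  )
  mf <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mf, precision = 15L)
  files["manifest"] <- mf
  invisible(files)
}

#' Write a run's recorded trajectory as tabular text
#'
#' @param run A `spine_run` with recorded weights.
#' @param path Output file (tab-separated long format: day, cluster,
#'   synapse, weight, status and, when recorded, `w_pre`/`dw`).
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(run, path) {
  stopifnot(inherits(run, "spine_run"))
  if (is.null(run$weights)) stop("run has no recorded weights", call. = FALSE)
  utils::write.table(as.data.frame(run$weights), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
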