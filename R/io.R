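#' Write a trace to CSV
#'
#' Traces are stored as plain CSV with full double precision, so a
#' write/read round trip preserves values to better than 1e-12 relative
#' error. Stimulus traces use columns `time_s`, `force_mN`; response
#' traces additionally `threshold_mN` and `rate_hz`. Extra columns are
#' kept.
#'
#' @param trace A `cs_stimulus` or `cs_response` (any tibble with a
#'   `time_s` column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Columns are matched by header name, so column order is free. The time
#' grid is validated (strictly increasing, uniform). A file with
#' `threshold_mN` and `rate_hz` columns is returned as a response trace,
#' otherwise as a stimulus.
#'
#' @param path CSV file path.
#' @return A `cs_stimulus` or `cs_response` tibble.
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "force_mN") %in% names(df))) {
    abort(paste0("trace file is missing mandatory columns time_s/force_mN: ",
                 path),
          class = "campaniform_input_error")
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    abort(paste0("non-monotone time column in ", path),
          class = "campaniform_input_error")
  }
  if (all(c("threshold_mN", "rate_hz") %in% names(df))) {
    out <- structure(df, class = c("cs_response", class(df)))
    validate_stimulus(out)
    return(out)
  }
  out <- structure(df, protocol = list(kind = "file", path = path),
                   class = c("cs_stimulus", class(df)))
  validate_stimulus(out)
}

#' Read and validate a run configuration
#'
#' A run configuration is a JSON object with fields `seed` (integer),
#' `model` (objects `agonist` and/or `antagonist` of model constants),
#' `protocol` (object with `kind` and the generator arguments), optional
#' `cuticle` (Zener constants) and optional `out_dir`. Validation happens
#' before any computation and errors name the offending field path.
#'
#' @param path JSON file path.
#' @return A validated config list of class `cs_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  fail <- function(field, msg) {
    abort(paste0("config field `", field, "`: ", msg),
          class = "campaniform_config_error")
  }
  if (is.null(cfg$seed)) fail("seed", "missing")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      cfg$seed != round(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  if (is.null(cfg$model) || !is.list(cfg$model)) fail("model", "missing")
  sgs <- intersect(names(cfg$model), c("agonist", "antagonist"))
  if (length(sgs) == 0L) {
    fail("model", "needs an `agonist` and/or `antagonist` entry")
  }
  model <- list()
  for (sg in sgs) {
    m <- cfg$model[[sg]]
    for (nm in c("a", "b", "c", "d", "tau")) {
      if (is.null(m[[nm]])) fail(paste0("model.", sg, ".", nm), "missing")
    }
    model[[sg]] <- tryCatch(
      as_cs_params(c(m, list(subgroup = sg))),
      campaniform_parameter_error = function(e) {
        fail(paste0("model.", sg), conditionMessage(e))
      })
  }
  cfg$model <- model
  if (is.null(cfg$protocol) || is.null(cfg$protocol$kind)) {
    fail("protocol.kind", "missing")
  }
  kinds <- c("ramp_hold", "staircase", "constant", "offset_series",
             "duration_series", "rate_series")
  if (!cfg$protocol$kind %in% kinds) {
    fail("protocol.kind", paste0("must be one of ",
                                 paste(kinds, collapse = ", ")))
  }
  if (!is.null(cfg$cuticle)) {
    cfg$cuticle <- tryCatch(
      as_zener_params(cfg$cuticle),
      campaniform_parameter_error = function(e) {
        fail("cuticle", conditionMessage(e))
      })
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("cs_config", "list"))
}

# Build the single-trace protocol named by a config.
protocol_from_config <- function(proto) {
  args <- proto[setdiff(names(proto), "kind")]
  switch(proto$kind,
         ramp_hold = do.call(stim_ramp_hold, args),
         staircase = do.call(stim_staircase, args),
         constant = do.call(stim_constant, args),
         abort(paste0("protocol kind `", proto$kind,
                      "` is an experiment; use cmd_experiment()"),
               class = "campaniform_config_error"))
}

run_manifest <- function(cfg) {
  list(config_hash = rlang::hash(unclass(cfg)),
       seed = cfg$seed,
       package = "campaniform",
       version = as.character(utils::packageVersion("campaniform")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Simulate a configured protocol and write the outputs
#'
#' Generates the configured stimulus, simulates each configured subgroup,
#' and writes per-subgroup response CSVs, a metrics CSV, a summary JSON
#' and a reproducibility manifest (config hash, seed, versions) into
#' `out_dir`. Deterministic paths are byte-identical across re-runs of the
#' same config.
#'
#' @param cfg A config list or path to a JSON config.
#' @param out_dir Output directory (created if needed); defaults to the
#'   config's `out_dir`.
#' @return Invisibly, a named list of written file paths.
#' @export
cmd_simulate <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir %||%
    abort("config field `out_dir`: missing",
          class = "campaniform_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stim <- protocol_from_config(cfg$protocol)
  paths <- list()
  metrics <- purrr::imap_dfr(cfg$model, function(p, sg) {
    resp <- simulate_response(stim, p, x0 = "adapted")
    f <- file.path(out_dir, paste0("response_", sg, ".csv"))
    write_trace(resp, f)
    paths[[paste0("response_", sg)]] <<- f
    epoch_metrics(resp)
  })
  paths$metrics <- file.path(out_dir, "metrics.csv")
  readr::write_csv(metrics, paths$metrics)
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(protocol = cfg$protocol$kind,
                            subgroups = names(cfg$model),
                            n_samples = nrow(stim),
                            metrics = metrics),
                       paths$summary, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run_manifest(cfg), paths$manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run a named simulated experiment from a config and write the outputs
#'
#' Runs the full protocol battery for the configured subgroups and writes
#' the metrics table, a figure, and a manifest into `out_dir`.
#'
#' @param name Experiment name (`"offset_series"`, `"duration_series"`,
#'   `"rate_series"`, `"staircase"`).
#' @param cfg A config list or path to a JSON config; experiment arguments
#'   are taken from `cfg$protocol` (minus `kind`).
#' @param out_dir Output directory; defaults to the config's `out_dir`.
#' @return Invisibly, the experiment's metrics tibble.
#' @export
cmd_experiment <- function(name, cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir %||%
    abort("config field `out_dir`: missing",
          class = "campaniform_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  args <- cfg$protocol[setdiff(names(cfg$protocol), "kind")]
  args$params <- cfg$model
  if (length(setdiff(c("agonist", "antagonist"), names(cfg$model)))) {
    args$params <- utils::modifyList(default_subgroups(), cfg$model)
  }
  ex <- do.call(run_experiment, c(list(name = name), args))
  mpath <- file.path(out_dir, paste0(name, "_metrics.csv"))
  readr::write_csv(ex$metrics, mpath)
  fig <- tryCatch(autoplot(ex), error = function(e) NULL)
  if (!is.null(fig)) {
    ggplot2::ggsave(file.path(out_dir, paste0(name, ".png")), fig,
                    width = 7, height = 5, dpi = 150)
  }
  jsonlite::write_json(run_manifest(cfg),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ex$metrics)
}
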