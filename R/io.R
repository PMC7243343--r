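#' Write a metric-record table to CSV
#'
#' Comma-separated, '.' decimal, UTF-8, header row, no index column. Numeric
#' columns are written with 17 significant digits so that reading the file
#' back reproduces the in-memory doubles exactly.
#'
#' @param records A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a metric-record CSV
#'
#' @param path CSV file written by [write_records_csv()].
#' @return A data frame with numeric columns restored.
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: msinet <subcommand> --out DIR [--seed INT] [--config FILE] [options]",
    "subcommands:",
    "  inverse-effectiveness  intensity sweep over the six conditions",
    "  spatial                spatial-principle offset x intensity sweep",
    "  within-modality        two-auditory-input sweep",
    "  scatter                enhancement vs additivity random draws",
    "  bayes                  cue-fusion experiment over a spec grid",
    "  fusion-offset          fusion probability vs spatial offset",
    "  spike-compare          spike backend vs rate model equilibria",
    "options: --intensities N --offsets a,b,... --lam a,b,... --samples N",
    "         --draws N --ticks N --n-steps N --noise X",
    sep = "\n")
}

CLI_SUBCOMMANDS <- c("inverse-effectiveness", "spatial", "within-modality",
                     "scatter", "bayes", "fusion-offset", "spike-compare")

parse_cli_args <- function(argv) {
  if (length(argv) == 0L) stop("missing subcommand\n", cli_usage(), call. = FALSE)
  sub <- argv[1L]
  if (!sub %in% CLI_SUBCOMMANDS) {
    stop("unknown subcommand '", sub, "'\n", cli_usage(), call. = FALSE)
  }
  known <- c("--out", "--seed", "--config", "--intensities", "--offsets",
             "--lam", "--samples", "--draws", "--ticks", "--n-steps", "--noise")
  opts <- list()
  rest <- argv[-1L]
  i <- 1L
  while (i <= length(rest)) {
    flag <- rest[i]
    if (!flag %in% known) stop("unknown flag '", flag, "'", call. = FALSE)
    if (i + 1L > length(rest)) stop("flag '", flag, "' needs a value", call. = FALSE)
    opts[[sub("^--", "", flag)]] <- rest[i + 1L]
    i <- i + 2L
  }
  list(subcommand = sub, opts = opts)
}

num_list <- function(s) as.numeric(strsplit(s, ",")[[1]])

# Resolve config file + flags into a run configuration. Flags win over the
# config file; unknown config keys are rejected.
resolve_run_config <- function(parsed) {
  opts <- parsed$opts
  cfg <- list()
  if (!is.null(opts$config)) cfg <- read_config_file(opts$config)
  legal <- c("params", "seed", "intensities", "offsets", "lam", "samples",
             "draws", "ticks", "n_steps", "noise")
  bad <- setdiff(names(cfg), legal)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  params_over <- if (is.null(cfg$params)) list() else cfg$params
  if (!is.null(opts[["n-steps"]])) params_over$n_steps <- as.integer(opts[["n-steps"]])
  get_num <- function(flag, key, default) {
    if (!is.null(opts[[flag]])) as.numeric(opts[[flag]])
    else if (!is.null(cfg[[key]])) as.numeric(cfg[[key]])
    else default
  }
  list(
    params = params_from_list(params_over),
    seed = as.integer(get_num("seed", "seed", 1)),
    n_intensities = as.integer(get_num("intensities", "intensities", 11)),
    offsets = if (!is.null(opts$offsets)) num_list(opts$offsets)
              else if (!is.null(cfg$offsets)) as.numeric(cfg$offsets) else 0:5,
    lam_values = if (!is.null(opts$lam)) num_list(opts$lam)
                 else if (!is.null(cfg$lam)) as.numeric(cfg$lam)
                 else c(0, 0.1, 0.2, 0.4, 0.6, 0.8),
    n_samples = as.integer(get_num("samples", "samples", 50)),
    n_draws = as.integer(get_num("draws", "draws", 200)),
    ticks = as.integer(get_num("ticks", "ticks", 1024)),
    noise = get_num("noise", "noise", 0)
  )
}

run_cli_experiment <- function(sub, rc) {
  p <- rc$params
  switch(sub,
    "inverse-effectiveness" = {
      sw <- run_inverse_effectiveness(p, rc$n_intensities)
      list(records = sw$records,
           summary = list(crossover_intensity = sw$crossover_intensity))
    },
    "spatial" = {
      sw <- run_spatial_principle(p, rc$offsets, rc$n_intensities)
      list(records = sw$records,
           summary = list(
             index_range_by_offset = sw$settings$index_range_by_offset))
    },
    "within-modality" = {
      sw <- run_within_modality(p, rc$offsets, rc$n_intensities)
      list(records = sw$records, summary = list())
    },
    "scatter" = {
      recs <- run_enhancement_scatter(p, rc$n_samples, rc$seed)
      list(records = recs,
           summary = list(
             max_additivity_feedback_off =
               max(recs$response_additivity[!recs$feedback], na.rm = TRUE)))
    },
    "bayes" = {
      specs <- fusion_spec_grid(n_draws = rc$n_draws, seed = rc$seed)
      recs <- run_fusion_grid(specs, p)
      on <- recs[recs$feedback & !is.na(recs$mean_error), ]
      off <- recs[!recs$feedback & !is.na(recs$variance_error), ]
      list(records = recs,
           summary = list(
             mean_abs_mean_error_on = mean(abs(on$mean_error)),
             mean_abs_variance_error_on = mean(abs(on$variance_error)),
             mean_abs_variance_error_off = mean(abs(off$variance_error))))
    },
    "fusion-offset" = {
      recs <- run_fusion_vs_offset(p, rc$offsets, rc$n_draws, rc$seed,
                                   noise_level = rc$noise)
      list(records = recs, summary = list())
    },
    "spike-compare" = {
      cond <- condition_spec("bimodal_full", intensity = 0.4)
      inputs <- build_condition_inputs(cond, p$n_neurons)
      recs <- spike_compare(inputs, p, ticks_per_step = rc$ticks,
                            seed = rc$seed)
      list(records = recs,
           summary = list(max_abs_error = max(recs$abs_error),
                          mean_abs_error = mean(recs$abs_error)))
    }
  )
}

#' Command-line entry point
#'
#' Dispatches one of the experiment subcommands, writes `records.csv`,
#' `summary.json` and a `provenance.json` (resolved configuration, seed and
#' package version) into the output directory and returns an exit status:
#' 0 on success, 2 on a configuration error, 3 on numeric instability.
#' The thin wrapper script installed under `inst/cli/msinet` forwards
#' `commandArgs()` to this function and quits with the returned status.
#'
#' @param argv Character vector of command-line tokens (subcommand first).
#' @return Integer exit status, invisibly.
#' @export
#' @examples
#' \dontrun{
#' run_cli(c("inverse-effectiveness", "--out", "results", "--n-steps", "500"))
#' }
run_cli <- function(argv) {
  parsed <- tryCatch(parse_cli_args(argv), error = function(e) e)
  if (inherits(parsed, "error")) {
    message(conditionMessage(parsed))
    return(invisible(2L))
  }
  rc <- tryCatch(resolve_run_config(parsed), error = function(e) e)
  if (inherits(rc, "error")) {
    message(conditionMessage(rc))
    return(invisible(2L))
  }
  out_dir <- parsed$opts$out
  if (is.null(out_dir)) {
    message("--out DIR is required")
    return(invisible(2L))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- tryCatch(run_cli_experiment(parsed$subcommand, rc),
                  error = function(e) e)
  if (inherits(res, "error")) {
    message("simulation failed: ", conditionMessage(res))
    return(invisible(3L))
  }
  write_records_csv(res$records, file.path(out_dir, "records.csv"))
  write_json_file(res$summary, file.path(out_dir, "summary.json"))
  prov <- list(
    subcommand = parsed$subcommand,
    seed = rc$seed,
    params = unclass(rc$params),
    settings = rc[setdiff(names(rc), "params")],
    package_version = as.character(utils::packageVersion("msinet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write_json_file(prov, file.path(out_dir, "provenance.json"))
  invisible(0L)
}
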