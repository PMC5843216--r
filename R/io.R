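#' Read and write pressure logs
#'
#' Pressure logs are plain CSV with a mandatory header and columns `time_s`,
#' `reactor_id`, `pressure_bar` (plus an optional `flag`); timestamps are
#' seconds from the start of the run. Reading validates the file and names
#' the offending row in its error messages; a write/read round trip
#' preserves values exactly.
#'
#' @param path file path.
#' @param trace a [pressure_trace()].
#' @return `read_pressure_log()` returns a [pressure_trace()];
#'   `write_pressure_log()` returns `path` invisibly.
#' @export
read_pressure_log <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "reactor_id", "pressure_bar")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("pressure log %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  if (!is.numeric(df$time_s)) stopf("non-numeric time_s in %s", path)
  if (!is.numeric(df$pressure_bar)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$pressure_bar))))[1L]
    stopf("non-numeric pressure at row %d of %s", bad, path)
  }
  if (nrow(df) >= 2L && any(diff(df$time_s) <= 0)) {
    stopf("time regression at row %d of %s",
          which(diff(df$time_s) <= 0)[1L] + 1L, path)
  }
  pressure_trace(df$time_s, df$pressure_bar,
                 reactor_id = df$reactor_id,
                 flag = if ("flag" %in% names(df)) df$flag else "ok")
}

#' @rdname read_pressure_log
#' @export
write_pressure_log <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  utils::write.csv(format_numeric_cols(as.data.frame(trace)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 17 significant digits: doubles survive a write/read round trip bit-exactly
format_numeric_cols <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) formatC(x, digits = 17,
                                                     format = "g"), "")
    }
  }
  df
}

#' Read and write controller event logs
#'
#' CSV with columns `time_s`, `reactor_id`, `event_type`, `value`.
#'
#' @param path file path.
#' @param events an [event_log()].
#' @return `read_event_log()` returns an [event_log()].
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "reactor_id", "event_type", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("event log %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  event_log(df$time_s, df$event_type, df$value, df$reactor_id)
}

#' @rdname read_event_log
#' @export
write_event_log <- function(events, path) {
  stopifnot(inherits(events, "event_log"))
  utils::write.csv(format_numeric_cols(as.data.frame(events)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write processed outputs
#'
#' `write_volume_trace()` stores the cumulative normalized volume as CSV
#' (`time_d`, `volume_mL_STP`, `flag`); `write_rate_summary()` stores a
#' rate table with columns `reactor_id`, `slope_mL_d`, `r2`, `se_mL_d`,
#' `n_points`.
#'
#' @param volume a `volume_trace`.
#' @param rates data.frame of rate rows.
#' @param path file path.
#' @export
write_volume_trace <- function(volume, path) {
  utils::write.csv(as.data.frame(volume), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_volume_trace
#' @export
write_rate_summary <- function(rates, path) {
  utils::write.csv(as.data.frame(rates), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load a simulation/processing configuration file
#'
#' Reads a YAML key-value file describing a run: a `reactor:` block with
#' [reactor_config()] fields, an optional `production:` block
#' ([production_profile()] fields), an optional `artifacts:` block
#' ([artifact_spec()] fields, event lists as row-wise lists), and a
#' top-level `seed`. All reactor invariants are enforced at load time with
#' errors naming the field and bound; unknown keys raise a warning, not an
#' error.
#'
#' @param path YAML file path.
#' @return list with `config` ([reactor_config()]), `profile`
#'   ([production_profile()] or NULL), `artifacts` ([artifact_spec()] or
#'   NULL) and `seed` (or NULL).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("reactor", "production", "artifacts", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    warnf("ignoring unknown top-level key(s): %s",
          paste(unknown, collapse = ", "))
  }
  reactor <- raw$reactor
  if (is.null(reactor)) reactor <- list()
  known_fields <- names(formals(reactor_config))
  unknown <- setdiff(names(reactor), known_fields)
  if (length(unknown)) {
    warnf("ignoring unknown reactor field(s): %s",
          paste(unknown, collapse = ", "))
    reactor <- reactor[setdiff(names(reactor), unknown)]
  }
  config <- do.call(reactor_config, reactor)

  profile <- NULL
  if (!is.null(raw$production)) {
    pr <- raw$production
    profile <- production_profile(
      rate_mL_STP_d = unlist(pr$rate_mL_STP_d),
      kind = if (is.null(pr$kind)) "constant" else pr$kind,
      breakpoints_d = if (is.null(pr$breakpoints_d)) numeric() else
        unlist(pr$breakpoints_d),
      k_per_d = pr$k_per_d
    )
  }
  artifacts <- NULL
  if (!is.null(raw$artifacts)) {
    ar <- raw$artifacts
    rows_to_df <- function(x) {
      if (is.null(x)) return(NULL)
      do.call(rbind, lapply(x, function(row) as.data.frame(row)))
    }
    artifacts <- artifact_spec(
      spike_events = rows_to_df(ar$spike_events),
      step_events = rows_to_df(ar$step_events),
      leak_events = rows_to_df(ar$leak_events),
      spikes_per_day = if (is.null(ar$spikes_per_day)) 0 else
        ar$spikes_per_day,
      spike_magnitude_mbar = if (is.null(ar$spike_magnitude_mbar)) 15 else
        ar$spike_magnitude_mbar,
      seed = ar$seed
    )
  }
  list(config = config, profile = profile, artifacts = artifacts,
       seed = raw$seed)
}

#' Write a run manifest
#'
#' Every command-line run emits one JSON manifest capturing the package
#' version, the seed(s), a snapshot of the configuration, the input/output
#' paths and per-stage sample/flag counts — enough to re-run the command
#' bit-identically.
#'
#' @param path output path for the JSON manifest.
#' @param command subcommand name.
#' @param seed seed(s) used.
#' @param config configuration snapshot (list), or NULL.
#' @param inputs,outputs character vectors of paths.
#' @param counts named list of per-stage counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed = NULL, config = NULL,
                           inputs = character(), outputs = character(),
                           counts = list()) {
  manifest <- list(
    tool = "chemogas",
    version = as.character(utils::packageVersion("chemogas")),
    command = command,
    seed = seed,
    config = config,
    inputs = inputs,
    outputs = outputs,
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
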