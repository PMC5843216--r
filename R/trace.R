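#' Pressure trace
#'
#' A uniformly sampled series of absolute pressure readings for one reactor,
#' the raw product of the acquisition system (or its digital twin). Stored as
#' a data.frame with columns `time_s` (seconds from start, strictly
#' increasing, uniform), `pressure_bar` (absolute bar), `reactor_id` and a
#' per-sample quality `flag` (`"ok"`, `"degas"`, `"spike"` or `"gap"`).
#'
#' @param time_s timestamps in seconds from the start of the run.
#' @param pressure_bar absolute pressure readings; must lie in (0, 3.4], the
#'   sensor's accepted range.
#' @param reactor_id reactor label.
#' @param flag per-sample quality flags (recycled).
#' @return a data.frame of class `pressure_trace`.
#' @export
pressure_trace <- function(time_s, pressure_bar, reactor_id = "R1",
                           flag = "ok") {
  if (length(time_s) != length(pressure_bar)) {
    stopf("`time_s` and `pressure_bar` must have equal length")
  }
  if (length(time_s) >= 2L) {
    dt <- diff(time_s)
    if (any(dt <= 0)) {
      stopf("`time_s` must be strictly increasing (first violation at row %d)",
            which(dt <= 0)[1L] + 1L)
    }
    if (max(dt) - min(dt) > 0.01 * stats::median(dt)) {
      warnf("sampling interval varies by more than 1%%; gap-aware steps assumed")
    }
  }
  if (any(!is.finite(pressure_bar)) ||
      any(pressure_bar <= 0 | pressure_bar > 3.4)) {
    bad <- which(!is.finite(pressure_bar) |
                   pressure_bar <= 0 | pressure_bar > 3.4)[1L]
    stopf("pressure at row %d (%g bar) outside the sensor range (0, 3.4]",
          bad, pressure_bar[bad])
  }
  out <- data.frame(
    time_s = as.numeric(time_s),
    pressure_bar = as.numeric(pressure_bar),
    reactor_id = as.character(reactor_id),
    flag = as.character(flag),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pressure_trace", "data.frame")
  out
}

# Median sampling interval of a trace, in seconds.
trace_interval <- function(trace) {
  if (nrow(trace) < 2L) return(NA_real_)
  stats::median(diff(trace$time_s))
}

#' Controller/actuator event log
#'
#' Timestamped record of what the controller did: degassing start/stop,
#' feed and waste pulses, and manual sampling. Event times are nondecreasing
#' and every `degas_start` is paired with a later `degas_end`.
#'
#' @param time_s event times in seconds from start.
#' @param event_type one of `degas_start`, `degas_end`, `feed`, `waste`,
#'   `sample`.
#' @param value event payload (e.g. pulse volume in mL, pressure in bar).
#' @param reactor_id reactor label.
#' @return a data.frame of class `event_log`.
#' @export
event_log <- function(time_s = numeric(), event_type = character(),
                      value = numeric(), reactor_id = "R1") {
  types <- c("degas_start", "degas_end", "feed", "waste", "sample")
  if (length(event_type) && !all(event_type %in% types)) {
    stopf("unknown event type(s): %s",
          paste(setdiff(unique(event_type), types), collapse = ", "))
  }
  if (length(time_s) >= 2L && any(diff(time_s) < 0)) {
    stopf("event times must be nondecreasing")
  }
  n_start <- sum(event_type == "degas_start")
  n_end <- sum(event_type == "degas_end")
  if (n_start != n_end) {
    stopf("unbalanced degassing events: %d start(s), %d end(s)",
          n_start, n_end)
  }
  out <- data.frame(
    time_s = as.numeric(time_s),
    reactor_id = rep_len(as.character(reactor_id), length(time_s)),
    event_type = as.character(event_type),
    value = rep_len(as.numeric(value), length(time_s)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("event_log", "data.frame")
  out
}

# rbind event logs and re-sort by time (stable).
merge_event_logs <- function(...) {
  logs <- list(...)
  logs <- logs[vapply(logs, function(x) !is.null(x) && nrow(x) > 0, TRUE)]
  if (!length(logs)) return(event_log())
  df <- do.call(rbind, lapply(logs, as.data.frame))
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}
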