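#' Reactor configuration
#'
#' Describes one laboratory anaerobic chemostat monitored by headspace
#' pressure: vessel geometry, temperature, the hysteresis degassing
#' thresholds, the pressure sensor, the feed/waste pulse schedules, the
#' organic loading rate, and the dissolved-gas (Henry-law) pool that drives
#' post-degassing re-equilibration.
#'
#' Defaults reflect a typical mesophilic operation: 180 mL working volume
#' wasted at 12 mL/day (hydraulic retention time 15 days), degassing
#' triggered at 1.2 bar and released at 1.05 bar, a 20-s sensor with
#' 0.0015 bar quantization, and an organic loading rate of
#' 1.33 gCOD L^-1 d^-1.
#'
#' @param working_volume_mL liquid volume in mL. Values outside 50-200 mL
#'   raise a warning (the bench system was designed for that range) but are
#'   accepted.
#' @param headspace_volume_mL effective gas-phase volume in mL, including
#'   sensor-line dead volume. Must be supplied or defaulted explicitly; it is
#'   not derived from the bottle size.
#' @param temperature_K reactor temperature in kelvin (default 310.15 K,
#'   i.e. 37 C).
#' @param p_high_bar absolute pressure that triggers degassing (default 1.2).
#' @param p_low_bar absolute pressure at which degassing stops (default 1.05).
#' @param p_init_bar initial headspace pressure (default `p_low_bar`).
#' @param sampling_interval_s sensor sampling period in seconds (default 20).
#' @param sensor_resolution_bar sensor quantization step (default 0.0015).
#' @param sensor_noise_sd_bar SD of additive Gaussian sensor noise, applied
#'   before quantization (default half a quantization step).
#' @param degas_pump_rate_mL_min gas removal rate of the degassing pump, in
#'   mL/min at reactor conditions (default 30, which empties a 1.2 to 1.05
#'   bar cycle of a 50 mL headspace within one 20-s sample).
#' @param feed_pulses_per_day,feed_pulse_volume_mL feed pulse schedule
#'   (default 24 pulses of 0.5 mL).
#' @param waste_pulses_per_day,waste_pulse_volume_mL biomass wasting schedule
#'   (default 24 pulses of 0.5 mL, i.e. 12 mL/day).
#' @param olr_gCOD_L_d organic loading rate in gCOD per litre of working
#'   volume per day (default 1.33).
#' @param henry_capacity_mL_per_bar capacity of the dissolved-gas pool:
#'   mL (STP-equivalent) of gas held in the liquid per bar of headspace
#'   pressure at equilibrium (default 5, giving the small post-degassing
#'   re-equilibration bumps seen in real traces; set 0 to disable the
#'   pool).
#' @param reequil_rate_per_h first-order rate at which the dissolved pool
#'   relaxes toward equilibrium after a pressure change (default 1).
#'
#' @return an object of class `reactor_config` (a named list).
#' @examples
#' cfg <- reactor_config()
#' cfg$p_high_bar
#' # hydraulic retention time implied by the wasting schedule, in days:
#' cfg$working_volume_mL /
#'   (cfg$waste_pulses_per_day * cfg$waste_pulse_volume_mL)
#' @export
reactor_config <- function(working_volume_mL = 180,
                           headspace_volume_mL = 50,
                           temperature_K = 310.15,
                           p_high_bar = 1.2,
                           p_low_bar = 1.05,
                           p_init_bar = p_low_bar,
                           sampling_interval_s = 20,
                           sensor_resolution_bar = 0.0015,
                           sensor_noise_sd_bar = sensor_resolution_bar / 2,
                           degas_pump_rate_mL_min = 30,
                           feed_pulses_per_day = 24,
                           feed_pulse_volume_mL = 0.5,
                           waste_pulses_per_day = 24,
                           waste_pulse_volume_mL = 0.5,
                           olr_gCOD_L_d = 1.33,
                           henry_capacity_mL_per_bar = 5,
                           reequil_rate_per_h = 1) {
  cfg <- list(
    working_volume_mL = working_volume_mL,
    headspace_volume_mL = headspace_volume_mL,
    temperature_K = temperature_K,
    p_high_bar = p_high_bar,
    p_low_bar = p_low_bar,
    p_init_bar = p_init_bar,
    sampling_interval_s = sampling_interval_s,
    sensor_resolution_bar = sensor_resolution_bar,
    sensor_noise_sd_bar = sensor_noise_sd_bar,
    degas_pump_rate_mL_min = degas_pump_rate_mL_min,
    feed_pulses_per_day = feed_pulses_per_day,
    feed_pulse_volume_mL = feed_pulse_volume_mL,
    waste_pulses_per_day = waste_pulses_per_day,
    waste_pulse_volume_mL = waste_pulse_volume_mL,
    olr_gCOD_L_d = olr_gCOD_L_d,
    henry_capacity_mL_per_bar = henry_capacity_mL_per_bar,
    reequil_rate_per_h = reequil_rate_per_h
  )
  class(cfg) <- "reactor_config"
  validate_reactor_config(cfg)
}

#' Validate a reactor configuration
#'
#' Enforces the physical invariants of the bench system: the hysteresis
#' thresholds must satisfy 0 < p_low < p_high <= 1.5 bar (the vessel
#' pressure rating; the sensor itself accepts at most 3.4 bar), all volumes,
#' rates and the temperature must be strictly positive, and the sampling
#' interval must be positive. A working volume outside 50-200 mL only warns.
#'
#' @param cfg a `reactor_config`.
#' @return `cfg`, invisibly checked; errors name the offending field.
#' @export
validate_reactor_config <- function(cfg) {
  for (f in c("working_volume_mL", "headspace_volume_mL", "temperature_K",
              "p_high_bar", "p_low_bar", "p_init_bar", "sampling_interval_s",
              "sensor_resolution_bar", "degas_pump_rate_mL_min",
              "olr_gCOD_L_d")) {
    check_scalar(cfg[[f]], f)
  }
  for (f in c("sensor_noise_sd_bar", "henry_capacity_mL_per_bar",
              "feed_pulses_per_day",
              "feed_pulse_volume_mL", "waste_pulses_per_day",
              "waste_pulse_volume_mL", "reequil_rate_per_h")) {
    check_scalar(cfg[[f]], f, positive = FALSE)
    if (cfg[[f]] < 0) stopf("`%s` must be >= 0 (got %g)", f, cfg[[f]])
  }
  if (cfg$p_low_bar >= cfg$p_high_bar) {
    stopf("`p_low_bar` (%g) must be below `p_high_bar` (%g)",
          cfg$p_low_bar, cfg$p_high_bar)
  }
  if (cfg$p_high_bar > 1.5) {
    stopf("`p_high_bar` (%g) exceeds the vessel pressure rating of 1.5 bar",
          cfg$p_high_bar)
  }
  if (cfg$working_volume_mL < 50 || cfg$working_volume_mL > 200) {
    warnf("`working_volume_mL` (%g) is outside the designed 50-200 mL range",
          cfg$working_volume_mL)
  }
  cfg
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("<reactor_config>\n")
  cat(sprintf("  liquid %g mL, headspace %g mL, %.2f K\n",
              x$working_volume_mL, x$headspace_volume_mL, x$temperature_K))
  cat(sprintf("  degassing hysteresis: %.3f -> %.3f bar; pump %g mL/min\n",
              x$p_high_bar, x$p_low_bar, x$degas_pump_rate_mL_min))
  cat(sprintf("  sensor: %g s interval, %.4f bar step, noise SD %.5f bar\n",
              x$sampling_interval_s, x$sensor_resolution_bar,
              x$sensor_noise_sd_bar))
  cat(sprintf("  feed %g x %g mL/d, waste %g x %g mL/d, OLR %g gCOD/L/d\n",
              x$feed_pulses_per_day, x$feed_pulse_volume_mL,
              x$waste_pulses_per_day, x$waste_pulse_volume_mL,
              x$olr_gCOD_L_d))
  invisible(x)
}

#' Biogas production profile
#'
#' The simulator treats gas production as an exogenous time profile in mL of
#' biogas (expressed at standard conditions, 293.15 K / 1.013 bar) per day;
#' no microbial kinetics are modelled. Three shapes are offered:
#' `"constant"`, `"piecewise_constant"` (one rate per segment between
#' breakpoints) and `"first_order"` (exponentially decaying rate, as in a
#' depleting batch of substrate).
#'
#' @param rate_mL_STP_d production rate(s), mL (STP) per day; one value for
#'   `constant`/`first_order`, `length(breakpoints_d) + 1` values for
#'   `piecewise_constant`.
#' @param kind profile shape.
#' @param breakpoints_d strictly increasing change times in days
#'   (piecewise profiles).
#' @param k_per_d first-order decay constant in 1/day (`first_order`).
#' @return an object of class `production_profile`.
#' @examples
#' production_profile(8)
#' production_profile(c(10, 5), kind = "piecewise_constant",
#'                    breakpoints_d = 3)
#' @export
production_profile <- function(rate_mL_STP_d,
                               kind = c("constant", "piecewise_constant",
                                        "first_order"),
                               breakpoints_d = numeric(),
                               k_per_d = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(rate_mL_STP_d) || any(!is.finite(rate_mL_STP_d))) {
    stopf("`rate_mL_STP_d` must be finite numeric")
  }
  if (any(rate_mL_STP_d < 0)) stopf("production rates must be >= 0")
  if (kind == "piecewise_constant") {
    if (length(breakpoints_d) < 1L ||
        any(diff(breakpoints_d) <= 0) || any(breakpoints_d <= 0)) {
      stopf("`breakpoints_d` must be positive and strictly increasing")
    }
    if (length(rate_mL_STP_d) != length(breakpoints_d) + 1L) {
      stopf("piecewise profile needs length(breakpoints_d) + 1 rates")
    }
  } else if (length(rate_mL_STP_d) != 1L) {
    stopf("`%s` profile takes a single rate", kind)
  }
  if (kind == "first_order") {
    check_scalar(k_per_d, "k_per_d", positive = FALSE)
    if (k_per_d < 0) stopf("`k_per_d` must be >= 0")
  }
  structure(
    list(kind = kind, rate_mL_STP_d = rate_mL_STP_d,
         breakpoints_d = as.numeric(breakpoints_d), k_per_d = k_per_d),
    class = "production_profile"
  )
}

#' Instantaneous production rate of a profile
#'
#' @param profile a [production_profile()].
#' @param time_d time(s) in days since the start of the run.
#' @return rate(s) in mL (STP) per day, vectorized over `time_d`.
#' @export
profile_rate <- function(profile, time_d) {
  stopifnot(inherits(profile, "production_profile"))
  switch(profile$kind,
    constant = rep(profile$rate_mL_STP_d, length(time_d)),
    piecewise_constant = {
      idx <- findInterval(time_d, profile$breakpoints_d) + 1L
      profile$rate_mL_STP_d[idx]
    },
    first_order = profile$rate_mL_STP_d * exp(-profile$k_per_d * time_d)
  )
}

#' Artifact specification for simulated pressure logs
#'
#' Describes the technical disturbances seen in raw chemostat pressure logs,
#' so that the spike/leak handling of the processing pipeline can be
#' validated against known ground truth:
#'
#' * `spike_events` - transient excursions: the pressure reading deviates by
#'   `magnitude_mbar` for `duration_samples` samples and then reverts
#'   (e.g. a pump briefly pinching the sensor line).
#' * `step_events` - persistent level shifts: the reading changes by
#'   `magnitude_mbar` from `time_d` onward. Liquid sampling through the
#'   septum produces such a step (gas expands into the freed volume and the
#'   pressure does not recover), so these are logged as `sample` events.
#' * `leak_events` - slow sustained declines at `rate_mbar_min` between
#'   `start_d` and `end_d`; the lost pressure stays lost afterwards.
#'
#' Instead of explicit times, transient spikes may be placed uniformly at
#' random via `spikes_per_day` (reproducibly, through `seed`).
#'
#' @param spike_events data.frame with columns `time_d`, `magnitude_mbar`,
#'   `duration_samples` (or NULL).
#' @param step_events data.frame with columns `time_d`, `magnitude_mbar`
#'   (or NULL).
#' @param leak_events data.frame with columns `start_d`, `end_d`,
#'   `rate_mbar_min` (or NULL).
#' @param spikes_per_day average number of randomly placed transient spikes
#'   per day (default 0 = none).
#' @param spike_magnitude_mbar magnitude for randomly placed spikes
#'   (default 15; the sign is randomized).
#' @param seed integer used for random placement; required when
#'   `spikes_per_day > 0` and no seed is passed to [inject_artifacts()].
#' @return an object of class `artifact_spec`.
#' @export
artifact_spec <- function(spike_events = NULL, step_events = NULL,
                          leak_events = NULL, spikes_per_day = 0,
                          spike_magnitude_mbar = 15, seed = NULL) {
  as_df <- function(x, cols, name) {
    if (is.null(x)) {
      return(stats::setNames(as.data.frame(rep(list(numeric()), length(cols))),
                             cols))
    }
    x <- as.data.frame(x)
    if (!all(cols %in% names(x))) {
      stopf("`%s` needs columns %s", name, paste(cols, collapse = ", "))
    }
    x[cols]
  }
  spike_events <- as_df(spike_events,
                        c("time_d", "magnitude_mbar", "duration_samples"),
                        "spike_events")
  if (any(spike_events$duration_samples < 1)) {
    stopf("spike durations must be >= 1 sample")
  }
  step_events <- as_df(step_events, c("time_d", "magnitude_mbar"),
                       "step_events")
  leak_events <- as_df(leak_events, c("start_d", "end_d", "rate_mbar_min"),
                       "leak_events")
  if (any(leak_events$end_d <= leak_events$start_d)) {
    stopf("leak windows must have end_d > start_d")
  }
  structure(
    list(spike_events = spike_events, step_events = step_events,
         leak_events = leak_events, spikes_per_day = spikes_per_day,
         spike_magnitude_mbar = spike_magnitude_mbar, seed = seed),
    class = "artifact_spec"
  )
}
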