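#' Hysteresis degassing controller step
#'
#' One decision of the two-threshold controller that produces the familiar
#' sawtooth pressure trace: degassing starts when the (measured) headspace
#' pressure reaches `p_high_bar` and continues until it has fallen to
#' `p_low_bar`; in between, the mode is left unchanged.
#'
#' @param pressure_bar current absolute pressure reading.
#' @param mode current controller mode, `"idle"` or `"degassing"`.
#' @param config a [reactor_config()].
#' @return the next mode, `"idle"` or `"degassing"`.
#' @examples
#' cfg <- reactor_config()
#' step_controller(1.19, "idle", cfg)       # still idle
#' step_controller(1.20, "idle", cfg)       # trigger
#' step_controller(1.10, "degassing", cfg)  # keep pumping
#' step_controller(1.05, "degassing", cfg)  # release
#' @export
step_controller <- function(pressure_bar, mode = c("idle", "degassing"),
                            config) {
  mode <- match.arg(mode)
  if (!is.numeric(pressure_bar) || length(pressure_bar) != 1L ||
      !is.finite(pressure_bar) || pressure_bar <= 0) {
    stopf("invalid sensor reading: pressure must be a finite positive number")
  }
  if (mode == "idle" && pressure_bar >= config$p_high_bar) return("degassing")
  if (mode == "degassing" && pressure_bar <= config$p_low_bar) return("idle")
  mode
}

#' Evenly spaced pulse schedule
#'
#' Feed and biomass wasting are applied as small pulses spread over the day
#' (quasi-continuous operation); e.g. 24 pulses of 0.5 mL remove 12 mL per
#' day. Pulses are evenly spaced, the first one falling one interval after
#' the start.
#'
#' @param pulses_per_day number of pulses per day (>= 0).
#' @param pulse_volume_mL volume moved per pulse (>= 0).
#' @param duration_d schedule span in days (>= 0).
#' @param event_type `"feed"`, `"waste"` or `"sample"`.
#' @param reactor_id reactor label.
#' @return an [event_log()] with one row per pulse; `value` is the pulse
#'   volume in mL.
#' @examples
#' ev <- schedule_pulses(24, 0.5, 1)   # hourly wasting
#' sum(ev$value)                       # 12 mL per day
#' @export
schedule_pulses <- function(pulses_per_day, pulse_volume_mL, duration_d,
                            event_type = "waste", reactor_id = "R1") {
  check_scalar(pulses_per_day, "pulses_per_day", positive = FALSE)
  check_scalar(pulse_volume_mL, "pulse_volume_mL", positive = FALSE)
  check_scalar(duration_d, "duration_d", positive = FALSE)
  if (pulses_per_day < 0) stopf("`pulses_per_day` must be >= 0")
  if (pulse_volume_mL < 0) stopf("`pulse_volume_mL` must be >= 0")
  if (duration_d < 0) stopf("`duration_d` must be >= 0")
  n <- round(pulses_per_day * duration_d)
  if (n == 0) return(event_log())
  interval_s <- SECONDS_PER_DAY / pulses_per_day
  event_log(time_s = seq_len(n) * interval_s,
            event_type = rep(event_type, n),
            value = rep(pulse_volume_mL, n),
            reactor_id = reactor_id)
}

#' Simulate one pressure-monitored chemostat
#'
#' Digital twin of a single reactor. The headspace is tracked as the
#' STP-equivalent gas volume `G` (mL at 293.15 K and 1.013 bar), related to
#' the absolute pressure by the ideal-gas law
#' `P = G * 1.013 * T / (V_head * 293.15)`. Each sampling interval, biogas
#' production (from the exogenous `profile`) adds to `G` minus the flux into
#' a dissolved-gas pool `D`, which relaxes first-order toward its Henry-law
#' equilibrium `D* = henry_capacity * P`; this pool produces the small
#' re-equilibration bumps observed after each degassing. While the
#' hysteresis controller is in degassing mode, gas is pumped out at
#' `degas_pump_rate_mL_min` (at reactor conditions), stopping exactly at
#' `p_low_bar` if the pump would overshoot within a step. Integration uses
#' fixed explicit-Euler steps equal to the sampling interval, keeping
#' simulator state aligned with sensor samples.
#'
#' The sensor model adds Gaussian noise (`sensor_noise_sd_bar`) to the true
#' pressure and quantizes to multiples of `sensor_resolution_bar`. The
#' controller acts on the measured reading, as in the real acquisition loop.
#' The same `seed` reproduces the run bit-identically.
#'
#' @param config a [reactor_config()].
#' @param profile a [production_profile()].
#' @param artifacts optional [artifact_spec()]; disturbances are injected
#'   into the measured trace via [inject_artifacts()] and sampling steps are
#'   logged as `sample` events.
#' @param duration_d simulated span in days (> 0).
#' @param seed integer seed for sensor noise and artifact placement.
#' @param reactor_id reactor label.
#' @return a list of class `reactor_sim` with elements
#'   * `trace`: the measured [pressure_trace()] (noisy, quantized,
#'     artifact-laden),
#'   * `events`: ground-truth [event_log()] (degassing, feed, waste, sample),
#'   * `truth`: list with the noise-free pressure, cumulative produced and
#'     degassed STP volumes, the dissolved-pool series, the mass-balance
#'     residual and an overpressure flag.
#' @details If the true pressure ever exceeds the 1.5 bar vessel rating
#'   (pump too slow for the production rate), a warning is raised and
#'   `truth$overpressure` is set; the run still completes.
#'
#'   Gas mass balance closes to machine precision for every configuration:
#'   `produced == delta_G + degassed + delta_D`.
#' @export
simulate_reactor <- function(config, profile, artifacts = NULL,
                             duration_d, seed, reactor_id = "R1") {
  stopifnot(inherits(config, "reactor_config"),
            inherits(profile, "production_profile"))
  check_scalar(duration_d, "duration_d")
  dt <- config$sampling_interval_s
  n_steps <- round(duration_d * SECONDS_PER_DAY / dt)
  if (n_steps < 1) stopf("`duration_d` too short for the sampling interval")
  n <- n_steps + 1L
  time_s <- (0:n_steps) * dt

  # P = G * pf ; G in mL STP
  pf <- P_STANDARD_BAR * config$temperature_K /
    (config$headspace_volume_mL * T_STANDARD_K)
  G0 <- config$p_init_bar / pf
  D0 <- config$henry_capacity_mL_per_bar * config$p_init_bar
  G_low <- config$p_low_bar / pf

  # per-step production (mL STP), rate taken at the step start
  rates <- profile_rate(profile, time_s[seq_len(n_steps)] / SECONDS_PER_DAY)
  prod_step <- rates * dt / SECONDS_PER_DAY
  relax <- min(1, config$reequil_rate_per_h * dt / 3600)
  # pump capacity in mL STP per step, per bar of current pressure
  pump_stp_per_bar <- config$degas_pump_rate_mL_min * (dt / 60) *
    T_STANDARD_K / (P_STANDARD_BAR * config$temperature_K)

  noise <- with_seed(seed, stats::rnorm(n, 0, config$sensor_noise_sd_bar))

  P_true <- produced <- degassed <- dissolved <- numeric(n)
  P_meas <- numeric(n)
  G <- G0; D <- D0
  mode <- "idle"
  ev_time <- numeric(0); ev_type <- character(0); ev_val <- numeric(0)
  overpressure <- FALSE
  prod_cum <- 0; degas_cum <- 0

  for (i in seq_len(n)) {
    if (i > 1L) {
      P0 <- G * pf
      dD <- (config$henry_capacity_mL_per_bar * P0 - D) * relax
      G <- G + prod_step[i - 1L] - dD
      D <- D + dD
      prod_cum <- prod_cum + prod_step[i - 1L]
      if (mode == "degassing") {
        cap <- pump_stp_per_bar * P0
        removal <- min(cap, max(0, G - G_low))
        G <- G - removal
        degas_cum <- degas_cum + removal
      }
    }
    P <- G * pf
    if (P > 1.5) overpressure <- TRUE
    # the sensor saturates at its 3.4 bar rating
    meas <- min(3.4, quantize(P + noise[i], config$sensor_resolution_bar))
    P_true[i] <- P
    P_meas[i] <- meas
    produced[i] <- prod_cum
    degassed[i] <- degas_cum
    dissolved[i] <- D
    new_mode <- step_controller(meas, mode, config)
    if (new_mode != mode) {
      ev_time <- c(ev_time, time_s[i])
      ev_type <- c(ev_type,
                   if (new_mode == "degassing") "degas_start" else "degas_end")
      ev_val <- c(ev_val, meas)
      mode <- new_mode
    }
  }
  if (mode == "degassing") {
    # run ends mid-degassing: close the pair at the final sample
    ev_time <- c(ev_time, time_s[n])
    ev_type <- c(ev_type, "degas_end")
    ev_val <- c(ev_val, P_meas[n])
  }
  if (overpressure) {
    warnf("pressure exceeded the 1.5 bar vessel rating during simulation (degassing pump too slow for the production rate)")
  }

  degas_events <- event_log(ev_time, ev_type, ev_val, reactor_id)
  feed <- schedule_pulses(config$feed_pulses_per_day,
                          config$feed_pulse_volume_mL, duration_d,
                          "feed", reactor_id)
  waste <- schedule_pulses(config$waste_pulses_per_day,
                           config$waste_pulse_volume_mL, duration_d,
                           "waste", reactor_id)
  feed <- feed[feed$time_s <= time_s[n], , drop = FALSE]
  waste <- waste[waste$time_s <= time_s[n], , drop = FALSE]

  trace <- pressure_trace(time_s, P_meas, reactor_id)
  sample_ev <- NULL
  if (!is.null(artifacts)) {
    stopifnot(inherits(artifacts, "artifact_spec"))
    trace <- inject_artifacts(trace, artifacts, seed = seed + 1L)
    if (nrow(artifacts$step_events)) {
      sample_ev <- event_log(
        time_s = sort(artifacts$step_events$time_d * SECONDS_PER_DAY),
        event_type = rep("sample", nrow(artifacts$step_events)),
        value = artifacts$step_events$magnitude_mbar[
          order(artifacts$step_events$time_d)],
        reactor_id = reactor_id)
    }
  }
  events <- merge_event_logs(degas_events, feed, waste, sample_ev)

  truth <- list(
    time_s = time_s,
    pressure_bar = P_true,
    produced_mL_STP = produced,
    degassed_mL_STP = degassed,
    dissolved_mL_STP = dissolved,
    headspace_mL_STP = c(G0, G),
    mass_balance_residual_mL =
      produced[n] - ((G - G0) + degassed[n] + (D - D0)),
    overpressure = overpressure
  )
  structure(list(trace = trace, events = events, truth = truth,
                 config = config, seed = seed),
            class = "reactor_sim")
}

#' @export
print.reactor_sim <- function(x, ...) {
  n <- nrow(x$trace)
  span_d <- (x$trace$time_s[n] - x$trace$time_s[1]) / SECONDS_PER_DAY
  cat(sprintf("<reactor_sim> %s: %d samples over %.2f d, %d degassing events\n",
              x$trace$reactor_id[1], n, span_d,
              sum(x$events$event_type == "degas_start")))
  cat(sprintf("  produced %.2f mL STP, degassed %.2f mL STP, balance residual %.2e mL\n",
              x$truth$produced_mL_STP[n], x$truth$degassed_mL_STP[n],
              x$truth$mass_balance_residual_mL))
  invisible(x)
}

#' Inject measurement artifacts into a pressure trace
#'
#' Applies the disturbances of an [artifact_spec()] to a recorded trace:
#' transient spikes (deviate, then revert), persistent sampling steps, and
#' sustained leak ramps whose loss remains after the leak window closes.
#' Samples not touched by any event are returned bit-identical.
#'
#' @param trace a [pressure_trace()].
#' @param spec an [artifact_spec()].
#' @param seed seed for randomly placed spikes; defaults to `spec$seed`.
#' @return the modified [pressure_trace()].
#' @export
inject_artifacts <- function(trace, spec, seed = NULL) {
  stopifnot(inherits(trace, "pressure_trace"), inherits(spec, "artifact_spec"))
  n <- nrow(trace)
  t0 <- trace$time_s[1]
  t_end <- trace$time_s[n]
  p <- trace$pressure_bar

  idx_at <- function(time_d, what) {
    ts <- t0 + time_d * SECONDS_PER_DAY
    if (any(ts < t0 - 1e-9) || any(ts > t_end + 1e-9)) {
      stopf("%s at day(s) %s outside the trace span", what,
            paste(signif(time_d[ts < t0 | ts > t_end], 4), collapse = ", "))
    }
    # first sample at or after the event time
    pmin(n, findInterval(ts - 1e-9, trace$time_s) + 1L)
  }

  spikes <- spec$spike_events
  if (spec$spikes_per_day > 0) {
    use_seed <- if (!is.null(seed)) seed else spec$seed
    if (is.null(use_seed)) {
      stopf("random spike placement requires a seed")
    }
    span_d <- (t_end - t0) / SECONDS_PER_DAY
    n_rand <- round(spec$spikes_per_day * span_d)
    if (n_rand > 0) {
      rnd <- with_seed(use_seed, {
        data.frame(
          time_d = stats::runif(n_rand, 0, span_d),
          magnitude_mbar = sample(c(-1, 1), n_rand, replace = TRUE) *
            spec$spike_magnitude_mbar,
          duration_samples = rep(1, n_rand)
        )
      })
      spikes <- rbind(spikes, rnd)
    }
  }

  if (nrow(spikes)) {
    start <- idx_at(spikes$time_d, "spike event")
    for (k in seq_len(nrow(spikes))) {
      idx <- start[k] + seq_len(spikes$duration_samples[k]) - 1L
      if (max(idx) > n) stopf("spike event at day %g extends beyond the trace",
                              spikes$time_d[k])
      p[idx] <- p[idx] + spikes$magnitude_mbar[k] / 1000
    }
  }
  if (nrow(spec$step_events)) {
    start <- idx_at(spec$step_events$time_d, "sampling step")
    for (k in seq_len(nrow(spec$step_events))) {
      p[start[k]:n] <- p[start[k]:n] + spec$step_events$magnitude_mbar[k] / 1000
    }
  }
  if (nrow(spec$leak_events)) {
    lk <- spec$leak_events
    i0 <- idx_at(lk$start_d, "leak window")
    i1 <- idx_at(lk$end_d, "leak window")
    for (k in seq_len(nrow(lk))) {
      idx <- i0[k]:n
      elapsed_min <- pmin(trace$time_s[idx] - trace$time_s[i0[k]],
                          trace$time_s[i1[k]] - trace$time_s[i0[k]]) / 60
      p[idx] <- p[idx] - lk$rate_mbar_min[k] / 1000 * elapsed_min
    }
  }
  trace$pressure_bar <- p
  trace
}
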