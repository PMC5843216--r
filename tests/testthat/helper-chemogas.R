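# Shared fixtures, built in code.

# Configuration used for pipeline-validation scenarios: mesophilic reactor
# with a 50 mL headspace and the dissolved-gas pool disabled, so that the
# pipeline's estimate can be compared directly against the production rate
# (gas retained in the liquid is reactor physics, not a pipeline error).
validation_config <- function(...) {
  args <- utils::modifyList(
    list(temperature_K = 310.15, headspace_volume_mL = 50,
         henry_capacity_mL_per_bar = 0),
    list(...))
  do.call(reactor_config, args)
}

# Same, with the sensor made ideal (no noise, effectively no quantization).
ideal_sensor_config <- function(...) {
  args <- utils::modifyList(
    list(sensor_noise_sd_bar = 0, sensor_resolution_bar = 1e-12),
    list(...))
  do.call(validation_config, args)
}

# A clean sawtooth between p_low and p_high, rising in equal steps,
# dropping in a single sample; no noise.
clean_sawtooth <- function(n_cycles = 4, steps_up = 6, p_low = 1.05,
                           p_high = 1.2, dt = 20) {
  ramp <- seq(p_low, p_high, length.out = steps_up + 1)
  p <- c(rep(ramp, n_cycles), p_low)
  pressure_trace(seq_along(p) * dt - dt, p)
}

# mL (STP) held by one full hysteresis cycle of a given headspace
cycle_volume_mL <- function(v_head, temp_K, dp = 0.15) {
  v_head * dp / 1.013 * 293.15 / temp_K
}
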