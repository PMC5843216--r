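test_that("hysteresis controller switches only at its thresholds", {
  cfg <- reactor_config()
  expect_identical(step_controller(1.19, "idle", cfg), "idle")
  expect_identical(step_controller(1.20, "idle", cfg), "degassing")
  expect_identical(step_controller(1.35, "idle", cfg), "degassing")
  expect_identical(step_controller(1.10, "degassing", cfg), "degassing")
  expect_identical(step_controller(1.05, "degassing", cfg), "idle")
  # hysteresis: intermediate pressures leave the mode unchanged
  for (p in c(1.06, 1.12, 1.19)) {
    expect_identical(step_controller(p, "idle", cfg), "idle")
    expect_identical(step_controller(p, "degassing", cfg), "degassing")
  }
  expect_error(step_controller(NaN, "idle", cfg), "invalid sensor reading")
  expect_error(step_controller(-1, "idle", cfg), "invalid sensor reading")
})

test_that("reactor configuration enforces physical invariants", {
  expect_error(reactor_config(p_high_bar = 1.6), "1.5 bar")
  expect_error(reactor_config(p_low_bar = 1.3, p_high_bar = 1.2),
               "p_low_bar")
  expect_error(reactor_config(headspace_volume_mL = -5),
               "headspace_volume_mL")
  expect_error(reactor_config(sampling_interval_s = 0),
               "sampling_interval_s")
  expect_warning(reactor_config(working_volume_mL = 30), "50-200")
  # the default wasting schedule implies a 15-day hydraulic retention time
  cfg <- reactor_config()
  expect_equal(cfg$working_volume_mL /
                 (cfg$waste_pulses_per_day * cfg$waste_pulse_volume_mL), 15)
})

test_that("pulse schedules are evenly spaced and conserve daily volume", {
  ev <- schedule_pulses(24, 0.5, 1.0)
  expect_s3_class(ev, "event_log")
  expect_equal(nrow(ev), 24)
  expect_equal(sum(ev$value), 12)              # 12 mL per day
  expect_equal(unique(diff(ev$time_s)), 3600)  # hourly
  expect_equal(nrow(schedule_pulses(24, 0, 1.0)), 24)
  expect_equal(sum(schedule_pulses(24, 0, 1.0)$value), 0)
  ev2 <- schedule_pulses(3, 2.0, 2.0)
  expect_equal(nrow(ev2), 6)
  expect_equal(sum(ev2$value), 12)
  expect_error(schedule_pulses(24, -1, 1), ">= 0")
  expect_equal(nrow(schedule_pulses(0, 1, 5)), 0)
})

test_that("production profiles evaluate as declared", {
  expect_equal(profile_rate(production_profile(8), c(0, 3, 10)),
               rep(8, 3))
  pw <- production_profile(c(10, 5, 2), kind = "piecewise_constant",
                           breakpoints_d = c(2, 4))
  expect_equal(profile_rate(pw, c(0, 1.9, 2, 3.9, 4, 9)),
               c(10, 10, 5, 5, 2, 2))
  fo <- production_profile(10, kind = "first_order", k_per_d = 0.5)
  expect_equal(profile_rate(fo, 2), 10 * exp(-1))
  expect_error(production_profile(-1), ">= 0")
  expect_error(production_profile(c(1, 2), kind = "piecewise_constant",
                                  breakpoints_d = c(3, 2)),
               "strictly increasing")
})

test_that("zero production keeps pressure at p_init with no degassing", {
  cfg <- validation_config()
  sim <- simulate_reactor(cfg, production_profile(0), duration_d = 1,
                          seed = 11)
  expect_equal(sim$truth$pressure_bar,
               rep(cfg$p_init_bar, length(sim$truth$pressure_bar)))
  expect_equal(sum(sim$events$event_type == "degas_start"), 0)
  # measured trace deviates from p_init only by noise + quantization
  expect_lt(max(abs(sim$trace$pressure_bar - cfg$p_init_bar)), 0.006)
})

test_that("degassing frequency follows ideal-gas cycle arithmetic", {
  # each 0.15 bar cycle of a 50 mL headspace at 310.15 K holds
  # 50 * (0.15/1.013) * (293.15/310.15) = 6.998 mL STP, so 63.8 mL/d
  # produces ~9.1 events/day
  cfg <- validation_config()
  sim <- simulate_reactor(cfg, production_profile(63.8), duration_d = 5,
                          seed = 1)
  events_per_day <- sum(sim$events$event_type == "degas_start") / 5
  expect_equal(cycle_volume_mL(50, 310.15), 6.998, tolerance = 1e-3)
  expect_equal(events_per_day, 63.8 / 6.998, tolerance = 0.06)
})

test_that("gas mass balance closes to machine precision", {
  profiles <- list(
    production_profile(8),
    production_profile(c(20, 5), kind = "piecewise_constant",
                       breakpoints_d = 1),
    production_profile(30, kind = "first_order", k_per_d = 0.3)
  )
  configs <- list(
    validation_config(),
    reactor_config(temperature_K = 310.15, headspace_volume_mL = 50),
    reactor_config(temperature_K = 303.15, headspace_volume_mL = 120,
                   henry_capacity_mL_per_bar = 20, reequil_rate_per_h = 3)
  )
  for (cfg in configs) {
    for (pr in profiles) {
      sim <- simulate_reactor(cfg, pr, duration_d = 2, seed = 5)
      produced <- utils::tail(sim$truth$produced_mL_STP, 1)
      expect_lt(abs(sim$truth$mass_balance_residual_mL) / max(produced, 1),
                1e-9)
    }
  }
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- reactor_config(temperature_K = 310.15, headspace_volume_mL = 50)
  a <- simulate_reactor(cfg, production_profile(12), duration_d = 1, seed = 3)
  b <- simulate_reactor(cfg, production_profile(12), duration_d = 1, seed = 3)
  expect_identical(a$trace$pressure_bar, b$trace$pressure_bar)
  expect_identical(a$events, b$events)
  c <- simulate_reactor(cfg, production_profile(12), duration_d = 1, seed = 4)
  expect_false(identical(a$trace$pressure_bar, c$trace$pressure_bar))
})

test_that("sensor readings are integer multiples of the resolution", {
  cfg <- reactor_config(temperature_K = 310.15, headspace_volume_mL = 50)
  sim <- simulate_reactor(cfg, production_profile(20), duration_d = 1,
                          seed = 8)
  ratio <- sim$trace$pressure_bar / cfg$sensor_resolution_bar
  expect_lt(max(abs(ratio - round(ratio))), 1e-6)
})

test_that("pressure never exceeds the trigger by more than one sample's production", {
  cfg <- ideal_sensor_config()
  sim <- simulate_reactor(cfg, production_profile(80), duration_d = 2,
                          seed = 2)
  one_sample_bar <- 80 * (20 / 86400) * 1.013 * 310.15 / (50 * 293.15)
  expect_lte(max(sim$truth$pressure_bar),
             cfg$p_high_bar + one_sample_bar + 1e-9)
})

test_that("doubling the headspace halves the degassing frequency", {
  n_events <- function(v_head) {
    cfg <- ideal_sensor_config(headspace_volume_mL = v_head)
    sim <- simulate_reactor(cfg, production_profile(30), duration_d = 5,
                            seed = 6)
    sum(sim$events$event_type == "degas_start")
  }
  n1 <- n_events(50)
  n2 <- n_events(100)
  expect_lte(abs(n2 - n1 / 2), 1)
})

test_that("an undersized pump triggers an overpressure warning, not an error", {
  cfg <- validation_config(degas_pump_rate_mL_min = 0.001)
  expect_warning(
    sim <- simulate_reactor(cfg, production_profile(100), duration_d = 0.5,
                            seed = 9),
    "1.5 bar")
  expect_true(sim$truth$overpressure)
})

test_that("artifact injection modifies exactly the targeted samples", {
  cfg <- validation_config()
  sim <- simulate_reactor(cfg, production_profile(8), duration_d = 1,
                          seed = 10)
  tr <- sim$trace
  # empty spec: identity
  expect_identical(inject_artifacts(tr, artifact_spec())$pressure_bar,
                   tr$pressure_bar)
  # one transient +15 mbar spike, 1 sample
  spec <- artifact_spec(spike_events = data.frame(
    time_d = 0.5, magnitude_mbar = 15, duration_samples = 1))
  out <- inject_artifacts(tr, spec)
  idx <- which(out$pressure_bar != tr$pressure_bar)
  expect_length(idx, 1)
  expect_equal(out$pressure_bar[idx] - tr$pressure_bar[idx], 0.015)
  # a persistent sampling step shifts everything from its onset
  stepspec <- artifact_spec(step_events = data.frame(
    time_d = 0.5, magnitude_mbar = -15))
  out2 <- inject_artifacts(tr, stepspec)
  changed <- which(out2$pressure_bar != tr$pressure_bar)
  expect_equal(changed, seq(min(changed), nrow(tr)))
  expect_equal(unique(out2$pressure_bar[changed] - tr$pressure_bar[changed]),
               -0.015)
  # random placement is reproducible under the same seed
  rnd <- artifact_spec(spikes_per_day = 5, seed = 77)
  expect_identical(inject_artifacts(tr, rnd)$pressure_bar,
                   inject_artifacts(tr, rnd)$pressure_bar)
  # events outside the trace span are an error
  bad <- artifact_spec(spike_events = data.frame(
    time_d = 2.5, magnitude_mbar = 15, duration_samples = 1))
  expect_error(inject_artifacts(tr, bad), "outside the trace span")
})

test_that("leaks decline during their window and stay lost afterwards", {
  tr <- pressure_trace(seq(0, 200, 20), rep(1.1, 11))
  spec <- artifact_spec(leak_events = data.frame(
    start_d = 20 / 86400, end_d = 100 / 86400, rate_mbar_min = 3))
  out <- inject_artifacts(tr, spec)
  expect_equal(out$pressure_bar[1:2], c(1.1, 1.1))
  # 3 mbar/min for 80 s = 4 mbar total, then held
  expect_equal(out$pressure_bar[6], 1.1 - 0.004)
  expect_equal(out$pressure_bar[11], 1.1 - 0.004)
  expect_true(all(diff(out$pressure_bar[2:6]) < 0))
})
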