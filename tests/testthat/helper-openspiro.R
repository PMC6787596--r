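# Shared fixtures for the openspiro test suite. Everything is generated in
# code under fixed seeds; no data files.

quiet_cal <- function(sample_rate = 100) {
  default_calibration(sample_rate = sample_rate, noisy = FALSE)
}

# One-maneuver session trace (no tidal phase) for parameter-recovery tests.
maneuver_session <- function(params, seed = 1L, noisy = TRUE,
                             quantize = TRUE, n_maneuvers = 1) {
  cal <- default_calibration(noisy = noisy)
  sc <- session_script(tidal_duration = 0, rest_duration = 5,
                       n_maneuvers = n_maneuvers, rng_seed = seed)
  make_session(sc, cal = cal, params = params,
               maneuver_effects = rep(1, n_maneuvers), quantize = quantize)
}

# Build a raw_trace holding a given fused-flow time line on both pressure
# channels (noiseless forward model), with a rest prefix for zeroing.
flow_to_trace <- function(flow, sample_rate = 100, rest_s = 2,
                          quantize = TRUE) {
  cal <- quiet_cal(sample_rate)
  full <- c(numeric(rest_s * sample_rate), flow)
  t <- (seq_along(full) - 1) / sample_rate
  va <- pressure_to_voltage(flow_to_pressure(full, cal$pressure_a),
                            cal$pressure_a, quantize = quantize)
  vb <- pressure_to_voltage(flow_to_pressure(full, cal$pressure_b),
                            cal$pressure_b, quantize = quantize)
  ann <- data.frame(
    label = c("rest", "maneuver"),
    start_s = c(0, rest_s),
    end_s = c(rest_s, rest_s + (length(flow) - 1) / sample_rate))
  raw_trace(sample_rate, t, va, vb,
            rep(cal$gas_no$v_baseline, length(full)),
            rep(cal$gas_co$v_baseline, length(full)), ann)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
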