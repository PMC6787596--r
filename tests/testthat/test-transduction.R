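# Forward and inverse sensor transduction, dual-range fusion, gas inversion.

test_that("orifice law maps flow to signed quadratic pressure", {
  spec <- pressure_sensor_spec("A", 50, 900, orifice_coeff_k = 1,
                               v_offset = 0.2, v_span = 1)
  expect_identical(flow_to_pressure(0, spec), 0)
  expect_equal(flow_to_pressure(2, spec), 4)
  expect_equal(flow_to_pressure(-2, spec), -4)
  # monotone in |Q|
  q <- seq(0.1, 10, length.out = 50)
  expect_true(all(diff(flow_to_pressure(q, spec)) > 0))
})

test_that("noiseless unquantized round trip is the identity over each sensor range", {
  cal <- quiet_cal()
  for (ch in c("pressure_a", "pressure_b")) {
    spec <- cal[[ch]]
    set.seed(42)
    q <- runif(100, spec$flow_min / 60, spec$flow_max / 60)
    v <- pressure_to_voltage(flow_to_pressure(q, spec), spec, quantize = FALSE)
    q_back <- voltage_to_flow(v, spec)
    expect_lt(max(abs(q_back - q)), 1e-9)
    expect_true(all(flow_flags(q_back) == 0L))
  }
})

test_that("quantized round-trip error respects the propagated ADC bound", {
  cal <- default_calibration()
  for (ch in c("pressure_a", "pressure_b")) {
    spec <- cal[[ch]]
    set.seed(7)
    q <- runif(500, spec$flow_min / 60, spec$flow_max / 60)
    v <- pressure_to_voltage(flow_to_pressure(q, spec), spec, quantize = TRUE)
    err <- abs(as.numeric(voltage_to_flow(v, spec)) - q)
    expect_true(all(err <= quantization_flow_bound(q, spec) + 1e-12))
  }
})

test_that("voltage stage offsets, clips and quantizes as specified", {
  spec <- quiet_cal()$pressure_a
  step <- adc_step(spec)
  # zero pressure -> offset, up to one quantization step
  expect_equal(pressure_to_voltage(0, spec), round(spec$v_offset / step) * step)
  # saturation at full scale
  expect_equal(pressure_to_voltage(100, spec), spec$v_ref)
  expect_equal(pressure_to_voltage(-100, spec), 0)
  # all noiseless outputs land on the ADC grid
  set.seed(1)
  p <- runif(1000, -0.5, 1.5)
  v <- pressure_to_voltage(p, spec)
  expect_lt(max(abs(v / step - round(v / step))), 1e-9)
  # noise is reproducible given a seed
  expect_identical(pressure_to_voltage(0.3, spec <- default_calibration()$pressure_a,
                                       noisy = TRUE, rng_seed = 5),
                   pressure_to_voltage(0.3, spec, noisy = TRUE, rng_seed = 5))
})

test_that("inverse flow clamps sub-offset voltages and flags out-of-range samples", {
  spec <- quiet_cal()$pressure_b
  expect_equal(as.numeric(voltage_to_flow(spec$v_offset, spec)), 0)
  expect_equal(as.numeric(voltage_to_flow(spec$v_offset - 0.05, spec)), 0)
  q <- voltage_to_flow(c(-0.1, 0.5, spec$v_ref + 0.2), spec)
  expect_identical(flow_flags(q), c(1L, 0L, 1L))
  expect_equal(as.numeric(q[1]), 0)  # clamped, not propagated as garbage
})

test_that("dual-range fusion selects the right sensor per flow regime", {
  cal <- quiet_cal()
  inv <- function(q, spec)
    as.numeric(voltage_to_flow(pressure_to_voltage(
      flow_to_pressure(q, spec), spec, quantize = FALSE), spec))
  n <- 50
  # 30 L/min: below the band -> exactly sensor B's estimate
  qa <- rep(inv(30 / 60, cal$pressure_a), n)
  qb <- rep(inv(30 / 60, cal$pressure_b), n)
  expect_identical(as.numeric(fuse_dual_sensors(qa, qb, cal)), qb)
  # 200 L/min: above the band -> exactly sensor A's estimate
  qa <- rep(inv(200 / 60, cal$pressure_a), n)
  qb <- rep(inv(200 / 60, cal$pressure_b), n)  # saturated, ignored
  expect_identical(as.numeric(fuse_dual_sensors(qa, qb, cal)), qa)
  # midpoint of the band blends half-and-half
  fused <- fuse_dual_sensors(76 / 60, 74 / 60, cal, q_ref = 75 / 60)
  expect_equal(as.numeric(fused) * 60, 75)
  expect_error(fuse_dual_sensors(1:3 / 10, 1:4 / 10, cal), "lengths differ")
})

test_that("fused flow is continuous through the cross-fade band", {
  cal <- quiet_cal()
  q_true <- seq(0, 5, by = 1 / 100)  # sweeps through the 50-100 L/min band
  qa <- voltage_to_flow(pressure_to_voltage(
    flow_to_pressure(q_true, cal$pressure_a), cal$pressure_a), cal$pressure_a)
  qb <- voltage_to_flow(pressure_to_voltage(
    flow_to_pressure(q_true, cal$pressure_b), cal$pressure_b), cal$pressure_b)
  fused <- as.numeric(fuse_dual_sensors(qa, qb, cal))
  jump <- max(abs(diff(fused)))
  single <- max(max(abs(diff(as.numeric(qa)))), max(abs(diff(as.numeric(qb)))))
  blend_err <- max(abs(as.numeric(qa) - as.numeric(qb))[
    q_true * 60 >= 50 & q_true * 60 <= 100])
  expect_lte(jump, single + blend_err + 1e-12)
})

test_that("gas inversion is linear, clamped at zero, and floor-flagged", {
  cal <- quiet_cal()
  no <- cal$gas_no; co <- cal$gas_co
  # baseline voltage -> zero concentration, flagged below floor
  c0 <- gas_voltage_to_concentration(no$v_baseline, no)
  expect_equal(as.numeric(c0), 0)
  expect_true(attr(c0, "below_floor"))
  # exact linearity: doubling (V - baseline) doubles the concentration
  v <- no$v_baseline + c(0.1, 0.25, 0.8)
  c1 <- as.numeric(gas_voltage_to_concentration(v, no))
  c2 <- as.numeric(gas_voltage_to_concentration(2 * v - no$v_baseline, no))
  expect_equal(c2, 2 * c1)
  # forward then inverse at 3.0 ppm CO, noiseless and unquantized
  v3 <- concentration_to_gas_voltage(3.0, co, quantize = FALSE)
  expect_lt(abs(as.numeric(gas_voltage_to_concentration(v3, co)) - 3.0), 1e-9)
  # 0.02 ppm NO sits below the 0.03 ppm floor: retained but flagged
  v02 <- concentration_to_gas_voltage(rep(0.02, 20), no, quantize = FALSE)
  cc <- gas_voltage_to_concentration(v02, no)
  expect_true(all(attr(cc, "below_floor")))
  expect_true(all(as.numeric(cc) > 0))
})

test_that("spec constructors enforce their invariants", {
  expect_error(pressure_sensor_spec("A", 100, 50, 1, 0.2, 4.8),
               "flow_min")
  expect_error(pressure_sensor_spec("A", 50, 900, -1, 0.2, 4.8),
               "orifice_coeff_k")
  expect_error(pressure_sensor_spec("A", 50, 900, 1, 0.2, 4.8, adc_bits = 6),
               "adc_bits")
  expect_error(gas_sensor_spec("NO", 20, 0.5, 0.3, 0.2), "range_max")
  cal <- quiet_cal()
  expect_error(sensor_calibration(cal$pressure_a, cal$pressure_b, cal$gas_no,
                                  cal$gas_co, fusion_low_edge = 10,
                                  fusion_high_edge = 100),
               "overlap")
  expect_error(sensor_calibration(cal$pressure_a, cal$pressure_b, cal$gas_no,
                                  cal$gas_co, sample_rate = 20),
               "sample_rate")
})
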