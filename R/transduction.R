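#' Flow to differential pressure (orifice law)
#'
#' The fixed airflow obstruction obeys the quadratic orifice-plate relation
#' `dP = k * Q^2 * sign(Q)`: pressure drop grows with the square of flow and
#' carries the sign of the flow direction (exhalation positive).
#'
#' @param flow Flow in L/s (signed; exhalation positive). Vectorised.
#' @param spec A [pressure_sensor_spec()].
#' @return Differential pressure in the spec's pressure units.
#' @export
flow_to_pressure <- function(flow, spec) {
  stopifnot(inherits(spec, "pressure_sensor_spec"))
  spec$orifice_coeff_k * flow^2 * sign(flow)
}

#' Differential pressure to sensor voltage
#'
#' Linear piezoresistive transfer plus optional Gaussian noise, clipped to
#' the ADC input range and quantized to `adc_bits` levels:
#' `V = clip(v_offset + v_span * p + noise, 0, v_ref)`. Deterministic for a
#' given `rng_seed`.
#'
#' @param p Pressure series (spec pressure units).
#' @param spec A [pressure_sensor_spec()].
#' @param noisy Add Gaussian voltage noise with SD `spec$noise_sd`?
#' @param rng_seed Optional integer seed used when `noisy = TRUE`.
#' @param quantize Quantize to the ADC grid (step `v_ref / (2^adc_bits - 1)`)?
#' @return Voltage series, V.
#' @export
pressure_to_voltage <- function(p, spec, noisy = FALSE, rng_seed = NULL,
                                quantize = TRUE) {
  stopifnot(inherits(spec, "pressure_sensor_spec"))
  v <- spec$v_offset + spec$v_span * p
  if (noisy && spec$noise_sd > 0) {
    noise <- if (is.null(rng_seed)) stats::rnorm(length(v), 0, spec$noise_sd)
             else with_seed(rng_seed, stats::rnorm(length(v), 0, spec$noise_sd))
    v <- v + noise
  }
  v <- pmin(pmax(v, 0), spec$v_ref)
  if (quantize) {
    step <- adc_step(spec)
    v <- round(v / step) * step
  }
  v
}

#' ADC quantization step
#'
#' @param spec A [pressure_sensor_spec()].
#' @return Voltage per ADC level, `v_ref / (2^adc_bits - 1)`.
#' @export
adc_step <- function(spec) spec$v_ref / (2^spec$adc_bits - 1)

#' Sensor voltage to flow (inverse transduction)
#'
#' Inverts the linear voltage stage and the quadratic orifice law:
#' `Q = sqrt(max((V - v_offset) / v_span, 0) / k)`.  Voltages below the
#' offset (negative pressure, i.e. inhalation, or downward noise) map to
#' zero flow, because only forced exhalation is analysed.  Voltages outside
#' `[0, v_ref]` are clamped and flagged rather than raising an error, so a
#' streamed trace survives isolated glitches.
#'
#' @param v Voltage series, V.
#' @param spec A [pressure_sensor_spec()].
#' @return Flow series in L/s with an integer attribute `"flags"`
#'   (0 = ok, 1 = voltage outside `[0, v_ref]`); retrieve with [flow_flags()].
#' @export
voltage_to_flow <- function(v, spec) {
  stopifnot(inherits(spec, "pressure_sensor_spec"))
  flags <- as.integer(v < 0 | v > spec$v_ref)
  v <- pmin(pmax(v, 0), spec$v_ref)
  p <- pmax((v - spec$v_offset) / spec$v_span, 0)
  q <- sqrt(p / spec$orifice_coeff_k)
  attr(q, "flags") <- flags
  q
}

#' Per-sample quality flags of an inverted flow series
#'
#' @param flow A series returned by [voltage_to_flow()] or
#'   [reconstruct_flow()].
#' @return Integer vector (0 = ok, nonzero = flagged sample).
#' @export
flow_flags <- function(flow) {
  f <- attr(flow, "flags")
  if (is.null(f)) integer(length(flow)) else f
}

#' Fuse the dual-range flow estimates
#'
#' Below the fusion band the low-range sensor B estimate is used, above it
#' the high-range sensor A estimate; inside the band the two are linearly
#' cross-faded with weight `w = (Q_ref - low) / (high - low)` applied as
#' `(1 - w) * B + w * A`.  The reference flow `Q_ref` steering the blend is
#' sensor A's estimate (valid over the whole high range, so the weight does
#' not depend on the saturating low-range channel).
#'
#' @param flow_a,flow_b Flow estimates from sensors A and B, L/s, equal
#'   length.
#' @param cal A [sensor_calibration()] providing the fusion band (L/min).
#' @param q_ref Reference flow steering the blend weight, L/s; defaults to
#'   sensor A's estimate.
#' @return Fused flow series, L/s; sample flags are the elementwise maximum
#'   of the input flags.
#' @export
fuse_dual_sensors <- function(flow_a, flow_b, cal, q_ref = flow_a) {
  stopifnot(inherits(cal, "sensor_calibration"))
  if (length(flow_a) != length(flow_b))
    stopf("fuse_dual_sensors: flow series lengths differ (%d vs %d)",
          length(flow_a), length(flow_b))
  lo <- cal$fusion_low_edge / LPM_PER_LPS
  hi <- cal$fusion_high_edge / LPM_PER_LPS
  w <- pmin(pmax((as.numeric(q_ref) - lo) / (hi - lo), 0), 1)
  fused <- (1 - w) * as.numeric(flow_b) + w * as.numeric(flow_a)
  attr(fused, "flags") <- pmax(flow_flags(flow_a), flow_flags(flow_b))
  fused
}

#' Gas sensor voltage to concentration
#'
#' Inverts the linear electrochemical transfer:
#' `C = (V - v_baseline) / sensitivity`, clamped at zero.  Samples below the
#' sensor's detection floor are flagged but retained.
#'
#' @param v Voltage series, V.
#' @param spec A [gas_sensor_spec()].
#' @return Concentration series in ppm with logical attribute
#'   `"below_floor"`.
#' @export
gas_voltage_to_concentration <- function(v, spec) {
  stopifnot(inherits(spec, "gas_sensor_spec"))
  conc <- pmax((v - spec$v_baseline) / spec$sensitivity, 0)
  attr(conc, "below_floor") <- conc < spec$detection_floor
  conc
}

#' Concentration to gas sensor voltage (forward model)
#'
#' @param conc Concentration series, ppm.
#' @param spec A [gas_sensor_spec()].
#' @param noisy Add Gaussian voltage noise with SD `spec$noise_sd`?
#' @param rng_seed Optional integer seed.
#' @param v_ref,adc_bits ADC model shared with the pressure channels.
#' @param quantize Quantize to the ADC grid?
#' @return Voltage series, V.
#' @export
concentration_to_gas_voltage <- function(conc, spec, noisy = FALSE,
                                         rng_seed = NULL, v_ref = 5,
                                         adc_bits = 10L, quantize = TRUE) {
  stopifnot(inherits(spec, "gas_sensor_spec"))
  v <- spec$v_baseline + spec$sensitivity * conc
  if (noisy && spec$noise_sd > 0) {
    noise <- if (is.null(rng_seed)) stats::rnorm(length(v), 0, spec$noise_sd)
             else with_seed(rng_seed, stats::rnorm(length(v), 0, spec$noise_sd))
    v <- v + noise
  }
  v <- pmin(pmax(v, 0), v_ref)
  if (quantize) {
    step <- v_ref / (2^as.integer(adc_bits) - 1)
    v <- round(v / step) * step
  }
  v
}

#' Analytic flow-error bound under ADC quantization
#'
#' For a noiseless in-range flow `Q > 0`, quantization perturbs the voltage
#' by at most half an ADC step; because the inverse map
#' `V -> sqrt((V - v_offset) / (v_span k))` is monotone, the recovered flow
#' lies between the inverses of `V +- step/2`. This returns the half-width
#' of that exact interval, the tight propagated bound used by the round-trip
#' tests.
#'
#' @param flow True flow, L/s (positive, in range).
#' @param spec A [pressure_sensor_spec()].
#' @return Maximum absolute flow error, L/s.
#' @export
quantization_flow_bound <- function(flow, spec) {
  step <- adc_step(spec)
  p <- flow_to_pressure(flow, spec)
  v <- spec$v_offset + spec$v_span * p
  inv <- function(vv) sqrt(pmax((pmin(pmax(vv, 0), spec$v_ref) - spec$v_offset) /
                                  spec$v_span, 0) / spec$orifice_coeff_k)
  pmax(abs(inv(v + step / 2) - flow), abs(inv(v - step / 2) - flow))
}
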