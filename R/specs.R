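#' Pressure sensor specification
#'
#' Describes one piezoresistive differential-pressure channel of the
#' pneumotachograph: the quadratic orifice coefficient relating flow to
#' pressure drop, the linear volts-per-pressure transfer of the bridge and
#' its offset, the ADC, and the validity range of the channel in L/min.
#'
#' The device carries two such channels: a high-range sensor ("A",
#' 50--900 L/min) and a low-range sensor ("B", 15--100 L/min), each covering
#' one section of the expected flow range.
#'
#' @param name Channel identifier, `"A"` (high range) or `"B"` (low range).
#' @param flow_min,flow_max Validity range of the channel, L/min.
#' @param orifice_coeff_k Orifice coefficient `k` in the quadratic law
#'   `dP = k * Q^2` (pressure units per (L/s)^2).
#' @param v_offset Output voltage at zero pressure, V.
#' @param v_span Volts per unit pressure, V.
#' @param noise_sd Additive voltage noise SD, V.
#' @param adc_bits ADC resolution in bits (>= 8).
#' @param v_ref ADC reference voltage, V.
#' @return An object of class `pressure_sensor_spec`.
#' @export
pressure_sensor_spec <- function(name, flow_min, flow_max, orifice_coeff_k,
                                 v_offset, v_span, noise_sd = 0,
                                 adc_bits = 10L, v_ref = 5) {
  stopifnot(is.character(name), length(name) == 1L)
  for (x in list(flow_min, flow_max, orifice_coeff_k, v_offset, v_span,
                 noise_sd, v_ref))
    if (!is_scalar_number(x)) stopf("pressure_sensor_spec: all numeric fields must be finite scalars")
  if (flow_min >= flow_max) stopf("pressure_sensor_spec: flow_min must be < flow_max")
  if (orifice_coeff_k <= 0) stopf("pressure_sensor_spec: orifice_coeff_k must be > 0")
  if (v_span <= 0) stopf("pressure_sensor_spec: v_span must be > 0")
  if (noise_sd < 0) stopf("pressure_sensor_spec: noise_sd must be >= 0")
  adc_bits <- as.integer(adc_bits)
  if (adc_bits < 8L) stopf("pressure_sensor_spec: adc_bits must be >= 8")
  structure(list(name = name, flow_min = flow_min, flow_max = flow_max,
                 orifice_coeff_k = orifice_coeff_k, v_offset = v_offset,
                 v_span = v_span, noise_sd = noise_sd, adc_bits = adc_bits,
                 v_ref = v_ref),
            class = "pressure_sensor_spec")
}

#' Gas sensor specification
#'
#' Linear model of an electrochemical gas cell behind a potentiostat and
#' transimpedance amplifier: the cell current is proportional to analyte
#' concentration and the electronics convert it to a voltage, so the lumped
#' transfer is a single volts-per-ppm sensitivity above a baseline voltage.
#'
#' @param analyte `"NO"` or `"CO"`.
#' @param sensitivity Volts per ppm (> 0).
#' @param v_baseline Output voltage at zero concentration, V.
#' @param detection_floor Lowest quantifiable concentration, ppm.
#' @param range_max Upper end of the calibrated range, ppm.
#' @param noise_sd Additive voltage noise SD, V.
#' @return An object of class `gas_sensor_spec`.
#' @export
gas_sensor_spec <- function(analyte, sensitivity, v_baseline,
                            detection_floor, range_max, noise_sd = 0) {
  analyte <- match.arg(analyte, c("NO", "CO"))
  if (sensitivity <= 0) stopf("gas_sensor_spec: sensitivity must be > 0")
  if (detection_floor < 0) stopf("gas_sensor_spec: detection_floor must be >= 0")
  if (range_max <= detection_floor)
    stopf("gas_sensor_spec: range_max must exceed detection_floor")
  if (noise_sd < 0) stopf("gas_sensor_spec: noise_sd must be >= 0")
  structure(list(analyte = analyte, sensitivity = sensitivity,
                 v_baseline = v_baseline, detection_floor = detection_floor,
                 range_max = range_max, noise_sd = noise_sd),
            class = "gas_sensor_spec")
}

#' Device calibration bundle
#'
#' Aggregates the two pressure channels, the two gas channels, the sampling
#' rate and the dual-range fusion band into one calibration object. The
#' fusion band must lie inside the overlap of the two pressure sensors'
#' validity ranges.
#'
#' @param pressure_a,pressure_b High- and low-range [pressure_sensor_spec()].
#' @param gas_no,gas_co NO and CO [gas_sensor_spec()].
#' @param sample_rate Sampling rate, Hz (>= 50).
#' @param fusion_low_edge,fusion_high_edge Cross-fade band, L/min.
#' @return An object of class `sensor_calibration`.
#' @seealso [default_calibration()]
#' @export
sensor_calibration <- function(pressure_a, pressure_b, gas_no, gas_co,
                               sample_rate = 100,
                               fusion_low_edge = 50, fusion_high_edge = 100) {
  stopifnot(inherits(pressure_a, "pressure_sensor_spec"),
            inherits(pressure_b, "pressure_sensor_spec"),
            inherits(gas_no, "gas_sensor_spec"),
            inherits(gas_co, "gas_sensor_spec"))
  if (sample_rate < 50) stopf("sensor_calibration: sample_rate must be >= 50 Hz")
  ov_lo <- max(pressure_a$flow_min, pressure_b$flow_min)
  ov_hi <- min(pressure_a$flow_max, pressure_b$flow_max)
  if (fusion_low_edge >= fusion_high_edge)
    stopf("sensor_calibration: fusion_low_edge must be < fusion_high_edge")
  if (fusion_low_edge < ov_lo || fusion_high_edge > ov_hi)
    stopf("sensor_calibration: fusion band [%g, %g] L/min must lie inside the sensors' overlap [%g, %g]",
          fusion_low_edge, fusion_high_edge, ov_lo, ov_hi)
  structure(list(pressure_a = pressure_a, pressure_b = pressure_b,
                 gas_no = gas_no, gas_co = gas_co,
                 sample_rate = sample_rate,
                 fusion_low_edge = fusion_low_edge,
                 fusion_high_edge = fusion_high_edge),
            class = "sensor_calibration")
}

#' Default device calibration profile
#'
#' The documented reference profile for the virtual device.  Each pressure
#' channel uses the quadratic orifice law with `k` chosen so that the
#' channel's full-scale flow maps to full ADC scale
#' (`v_offset + v_span * k * Q_max^2 = v_ref`): sensor A covers 50--900 L/min
#' and sensor B 15--100 L/min.  The ADC is 10-bit over 0--5 V and the default
#' sampling rate is 100 Hz.  The gas channels are calibrated to resolve the
#' lower end of the physiologic ranges (0.03 ppm NO, 2 ppm CO).
#'
#' @param sample_rate Sampling rate, Hz.
#' @param noisy If `FALSE`, all channel noise SDs are set to zero.
#' @return A [sensor_calibration()] object.
#' @export
default_calibration <- function(sample_rate = 100, noisy = TRUE) {
  nz <- if (noisy) 1 else 0
  a <- pressure_sensor_spec("A", 50, 900,
                            orifice_coeff_k = 4.8 / (4.8 * (900 / LPM_PER_LPS)^2),
                            v_offset = 0.2, v_span = 4.8,
                            noise_sd = 0.0008 * nz, adc_bits = 10L, v_ref = 5)
  b <- pressure_sensor_spec("B", 15, 100,
                            orifice_coeff_k = 4.8 / (4.8 * (100 / LPM_PER_LPS)^2),
                            v_offset = 0.2, v_span = 4.8,
                            noise_sd = 0.0008 * nz, adc_bits = 10L, v_ref = 5)
  no <- gas_sensor_spec("NO", sensitivity = 20, v_baseline = 0.5,
                        detection_floor = 0.03, range_max = 0.2,
                        noise_sd = 0.002 * nz)
  co <- gas_sensor_spec("CO", sensitivity = 0.4, v_baseline = 0.5,
                        detection_floor = 2, range_max = 10,
                        noise_sd = 0.002 * nz)
  sensor_calibration(a, b, no, co, sample_rate = sample_rate)
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat("<sensor_calibration>\n")
  cat(sprintf("  pressure A: %g-%g L/min, k=%.5g, offset %.3g V, span %.3g V\n",
              x$pressure_a$flow_min, x$pressure_a$flow_max,
              x$pressure_a$orifice_coeff_k, x$pressure_a$v_offset,
              x$pressure_a$v_span))
  cat(sprintf("  pressure B: %g-%g L/min, k=%.5g, offset %.3g V, span %.3g V\n",
              x$pressure_b$flow_min, x$pressure_b$flow_max,
              x$pressure_b$orifice_coeff_k, x$pressure_b$v_offset,
              x$pressure_b$v_span))
  cat(sprintf("  gas NO: %.3g V/ppm, floor %.3g ppm; gas CO: %.3g V/ppm, floor %.3g ppm\n",
              x$gas_no$sensitivity, x$gas_no$detection_floor,
              x$gas_co$sensitivity, x$gas_co$detection_floor))
  cat(sprintf("  sample rate %g Hz, fusion band %g-%g L/min\n",
              x$sample_rate, x$fusion_low_edge, x$fusion_high_edge))
  invisible(x)
}
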