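# Physiologic reference ranges (ppm) for exhaled breath biomarkers:
# NO 0.03-0.13 ppm (30-130 ppb), CO 2-7 ppm.
physiologic_ranges <- function() {
  list(NO = c(0.03, 0.13), CO = c(2, 7))
}

#' Summarise a gas concentration window
#'
#' Computes the windowed breath-gas estimate from a concentration series:
#' mean and SD over the window after discarding an initial equilibration
#' span (the electrochemical cells need several seconds to equilibrate
#' after the subject engages the mouthpiece), the fraction of samples
#' below the sensor's detection floor, and a physiologic-range flag.
#'
#' @param conc Concentration series for the whole trace, ppm (from
#'   [gas_voltage_to_concentration()]).
#' @param window Numeric `c(start_s, end_s)` of the tidal window, s.
#' @param spec The channel's [gas_sensor_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param phys_range Numeric `c(lo, hi)` physiologic range, ppm; defaults
#'   to the analyte's standard range.
#' @param equilibration_discard_s Initial span of the window discarded
#'   before summarising, s.
#' @return An object of class `gas_reading`: `analyte`, `mean_conc` (ppm),
#'   `mean_conc_ppb` (NO only, `1000 *` ppm), `sd_conc`, `window`,
#'   `n_samples`, `below_floor_fraction`, `in_physiologic_range`,
#'   `status`.
#' @export
summarize_gas_window <- function(conc, window, spec, sample_rate,
                                 phys_range = NULL,
                                 equilibration_discard_s = 10) {
  stopifnot(inherits(spec, "gas_sensor_spec"))
  if (is.null(phys_range)) phys_range <- physiologic_ranges()[[spec$analyte]]
  n <- length(conc)
  t <- (seq_len(n) - 1) / sample_rate
  if (diff(window) < 10)
    return(structure(list(analyte = spec$analyte,
                          status = "quantification-unavailable",
                          reason = "window shorter than 10 s"),
                     class = "gas_reading"))
  keep <- t >= window[1] + equilibration_discard_s & t <= window[2]
  x <- as.numeric(conc)[keep]
  bf <- attr(conc, "below_floor")
  bf <- if (is.null(bf)) x < spec$detection_floor else bf[keep]
  m <- mean(x)
  structure(list(analyte = spec$analyte, mean_conc = m,
                 mean_conc_ppb = if (spec$analyte == "NO") 1000 * m else NULL,
                 sd_conc = stats::sd(x),
                 window = window, n_samples = length(x),
                 below_floor_fraction = mean(bf),
                 in_physiologic_range = m >= phys_range[1] & m <= phys_range[2],
                 status = "ok"),
            class = "gas_reading")
}

#' @export
print.gas_reading <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<gas_reading %s> %s (%s)\n", x$analyte, x$status, x$reason))
    return(invisible(x))
  }
  unit <- if (x$analyte == "NO") sprintf("%.1f ppb", x$mean_conc_ppb)
          else sprintf("%.2f ppm", x$mean_conc)
  cat(sprintf("<gas_reading %s> mean %s (sd %.4g ppm, n = %d), %s physiologic range, %.0f%% below floor\n",
              x$analyte, unit, x$sd_conc, x$n_samples,
              if (x$in_physiologic_range) "in" else "OUT of",
              100 * x$below_floor_fraction))
  invisible(x)
}

#' Pool gas readings across sessions
#'
#' Cohort-level summary of a set of [summarize_gas_window()] readings.
#' Readings flagged unreliable (protocol-violating order or a majority of
#' samples below the detection floor) are excluded unless explicitly
#' included.
#'
#' @param readings List of `gas_reading` objects (with `reliable` flags as
#'   set by [analyze_gas()]).
#' @param include_flagged Include unreliable readings?
#' @return List with `mean` and `sem` of the per-reading means (ppm),
#'   `n_used`, `n_excluded`.
#' @export
pool_gas_readings <- function(readings, include_flagged = FALSE) {
  ok <- vapply(readings, function(r) {
    if (r$status != "ok") return(FALSE)
    include_flagged || isTRUE(r$reliable)
  }, logical(1))
  x <- vapply(readings[ok], function(r) r$mean_conc, numeric(1))
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
       n_used = length(x), n_excluded = sum(!ok))
}

#' Calibrate a gas sensor from known concentrations
#'
#' Least-squares line fit of measured voltage against known concentration;
#' the slope is the sensitivity (V/ppm) and the intercept the baseline
#' voltage. Fits with R-squared below the linearity threshold are rejected,
#' since the transduction model assumes a linear cell response.
#'
#' @param known_conc Known concentrations, ppm (>= 2 distinct values).
#' @param measured_v Measured voltages, V.
#' @param spec Optional [gas_sensor_spec()] to update.
#' @param r2_min Minimum R-squared accepted as linear.
#' @return List with `sensitivity`, `v_baseline`, `residual_rms`,
#'   `r_squared`, and `spec` (the updated spec when one was supplied).
#' @export
calibrate_gas_sensor <- function(known_conc, measured_v, spec = NULL,
                                 r2_min = 0.99) {
  if (length(known_conc) != length(measured_v))
    stopf("calibrate_gas_sensor: concentration and voltage lengths differ")
  if (length(unique(known_conc)) < 2)
    stopf("calibrate_gas_sensor: need >= 2 distinct concentrations")
  fit <- stats::lm(measured_v ~ known_conc)
  ss_tot <- sum((measured_v - mean(measured_v))^2)
  r2 <- if (ss_tot == 0) 1
        else 1 - sum(stats::residuals(fit)^2) / ss_tot
  if (r2 < r2_min)
    stopf("calibrate_gas_sensor: nonlinear sensor response (R-squared %.4f < %.2f)",
          r2, r2_min)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    stopf("calibrate_gas_sensor: fitted sensitivity is not positive")
  out <- list(sensitivity = slope,
              v_baseline = unname(stats::coef(fit)[1]),
              residual_rms = sqrt(mean(stats::residuals(fit)^2)),
              r_squared = r2)
  if (!is.null(spec)) {
    spec$sensitivity <- out$sensitivity
    spec$v_baseline <- out$v_baseline
    out$spec <- spec
  }
  out
}

#' Check the gas-before-spirometry protocol order
#'
#' Forced maneuvers artificially depress exhaled NO, so gas quantification
#' windows that start after any maneuver are flagged protocol-violating
#' (the NO estimate from such a window is unreliable).
#'
#' @param trace A [raw_trace()] (its annotations are inspected), or a
#'   `data.frame` of annotations.
#' @param gas_label Label of gas/tidal quantification windows.
#' @return `data.frame` with one row per gas window: `start_s`, `end_s`,
#'   `after_maneuver` (logical flag).
#' @export
sequence_check <- function(trace, gas_label = "tidal") {
  ann <- if (inherits(trace, "raw_trace")) trace$annotations else trace
  gas <- ann[ann$label == gas_label, , drop = FALSE]
  manv <- ann[ann$label == "maneuver", , drop = FALSE]
  first_maneuver <- if (nrow(manv)) min(manv$start_s) else Inf
  data.frame(start_s = gas$start_s, end_s = gas$end_s,
             after_maneuver = gas$start_s > first_maneuver)
}

#' Quantify exhaled NO and CO for a session
#'
#' Full gas pipeline: inverts both gas channels, summarises the annotated
#' tidal window, and applies the protocol-order check. NO readings from
#' protocol-violating windows are marked unreliable.
#'
#' @param trace A [raw_trace()] with a `tidal` annotation.
#' @param cal A [sensor_calibration()].
#' @param equilibration_discard_s Passed to [summarize_gas_window()].
#' @return List with `no` and `co` [summarize_gas_window()] readings (each
#'   with an added `reliable` flag) and `sequence` (the
#'   [sequence_check()] table).
#' @export
analyze_gas <- function(trace, cal = default_calibration(),
                        equilibration_discard_s = 10) {
  stopifnot(inherits(trace, "raw_trace"))
  ann <- trace$annotations
  tidal <- ann[ann$label == "tidal", , drop = FALSE]
  if (!nrow(tidal))
    return(list(no = structure(list(analyte = "NO",
                                    status = "quantification-unavailable",
                                    reason = "no tidal window"),
                               class = "gas_reading"),
                co = structure(list(analyte = "CO",
                                    status = "quantification-unavailable",
                                    reason = "no tidal window"),
                               class = "gas_reading"),
                sequence = sequence_check(trace)))
  win <- c(tidal$start_s[1], tidal$end_s[1])
  conc_no <- gas_voltage_to_concentration(trace$v_gas_no, cal$gas_no)
  conc_co <- gas_voltage_to_concentration(trace$v_gas_co, cal$gas_co)
  no <- summarize_gas_window(conc_no, win, cal$gas_no, trace$sample_rate,
                             equilibration_discard_s = equilibration_discard_s)
  co <- summarize_gas_window(conc_co, win, cal$gas_co, trace$sample_rate,
                             equilibration_discard_s = equilibration_discard_s)
  seq_tab <- sequence_check(trace)
  violated <- any(seq_tab$after_maneuver)
  no$reliable <- !violated && no$status == "ok" && no$below_floor_fraction < 0.5
  co$reliable <- co$status == "ok" && co$below_floor_fraction < 0.5
  list(no = no, co = co, sequence = seq_tab)
}
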