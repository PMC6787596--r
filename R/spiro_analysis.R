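#' Estimate per-channel zero offsets from the rest window
#'
#' Median voltage of each channel over the annotated rest window (the 5 s
#' pause before the device signals the maneuver), used as the zero-pressure
#' / baseline reference before inversion.  Falls back to the first two
#' seconds of the trace, with a warning, when no rest annotation exists.
#'
#' @param trace A [raw_trace()].
#' @param rest_label Annotation label of the rest window.
#' @return Named numeric vector of offsets (V) for `v_pressure_a`,
#'   `v_pressure_b`, `v_gas_no`, `v_gas_co`.
#' @export
estimate_zero_offset <- function(trace, rest_label = "rest") {
  stopifnot(inherits(trace, "raw_trace"))
  ann <- trace$annotations
  rest <- ann[ann$label == rest_label, , drop = FALSE]
  if (nrow(rest) >= 1) {
    w <- rest[1, ]
    if (w$end_s - w$start_s < 1)
      stopf("estimate_zero_offset: rest window must be >= 1 s")
    idx <- trace$t >= w$start_s & trace$t <= w$end_s
  } else {
    warning("no rest annotation; using the first 2 s of the trace for zeroing",
            call. = FALSE)
    idx <- trace$t <= trace$t[1] + 2
  }
  vapply(c("v_pressure_a", "v_pressure_b", "v_gas_no", "v_gas_co"),
         function(ch) stats::median(trace[[ch]][idx]), numeric(1))
}

#' Reconstruct fused flow from a raw trace
#'
#' Applies the estimated zero-offset correction to each pressure channel,
#' inverts the quadratic orifice law per sensor, and fuses the dual-range
#' estimates.  Voltages below the corrected offset (inhalation or downward
#' noise) map to zero flow: only forced exhalation is analysed.
#'
#' @param trace A [raw_trace()].
#' @param cal A [sensor_calibration()].
#' @param offsets Optional named offsets from [estimate_zero_offset()];
#'   estimated from the trace when `NULL`.
#' @return Fused flow series, L/s, with per-sample flags (see
#'   [flow_flags()]).
#' @export
reconstruct_flow <- function(trace, cal, offsets = NULL) {
  stopifnot(inherits(trace, "raw_trace"), inherits(cal, "sensor_calibration"))
  if (is.null(offsets)) offsets <- estimate_zero_offset(trace)
  spec_a <- cal$pressure_a; spec_a$v_offset <- offsets[["v_pressure_a"]]
  spec_b <- cal$pressure_b; spec_b$v_offset <- offsets[["v_pressure_b"]]
  qa <- voltage_to_flow(trace$v_pressure_a, spec_a)
  qb <- voltage_to_flow(trace$v_pressure_b, spec_b)
  fuse_dual_sensors(qa, qb, cal)
}

#' Cumulative exhaled volume from a flow series
#'
#' Cumulative trapezoidal integral of flow on a uniform grid; volume starts
#' at zero and is nondecreasing for nonnegative flow.
#'
#' @param flow Flow series, L/s.
#' @param sample_rate Sampling rate, Hz.
#' @return Volume series, L, same length as `flow`.
#' @export
integrate_volume <- function(flow, sample_rate) {
  cumtrapz_uniform(as.numeric(flow), 1 / sample_rate)
}

#' Back-extrapolated time zero and back-extrapolated volume
#'
#' Standard back-extrapolation: the tangent to the volume-time curve at the
#' point of maximal flow is extended back to the zero-volume axis; its
#' intercept defines the corrected start time `t0`, and the volume already
#' expired at `t0` (read off the measured volume curve) is the
#' back-extrapolated volume (BEV), a maneuver-quality indicator.
#'
#' @param volume Volume series, L (from [integrate_volume()]).
#' @param flow Flow series, L/s, same grid.
#' @param sample_rate Sampling rate, Hz.
#' @param t Optional time vector; defaults to a zero-based uniform grid.
#' @return List with `t0` (s, on the `t` axis), `bev` (L), and
#'   `peak_index`.
#' @export
detect_time_zero <- function(volume, flow, sample_rate, t = NULL) {
  flow <- as.numeric(flow)
  n <- length(flow)
  if (is.null(t)) t <- (seq_len(n) - 1) / sample_rate
  if (n < 2 || max(flow) <= 0)
    stopf("detect_time_zero: no detectable expiratory rise; maneuver unusable")
  im <- which.max(flow)
  slope <- flow[im]
  t0 <- t[im] - volume[im] / slope
  if (t0 < t[1]) t0 <- t[1]
  bev <- stats::approx(t, volume, xout = t0, rule = 2)$y
  list(t0 = t0, bev = bev, peak_index = im)
}

#' End-of-test detection (volume plateau)
#'
#' Finds the earliest sample after which the volume accumulated over every
#' trailing 1-s window stays below the plateau threshold (0.025 L over 1 s,
#' the conventional end-of-test criterion).  If no such point exists before
#' the segment runs out, the end of test is flagged not reached.
#'
#' @param volume Volume series, L.
#' @param sample_rate Sampling rate, Hz.
#' @param threshold Plateau threshold, L per 1-s window.
#' @return List with `index` (first quiet sample; `length(volume)` when no
#'   plateau was found) and `plateau_reached` (logical).
#' @export
end_of_test <- function(volume, sample_rate, threshold = 0.025) {
  n <- length(volume)
  win <- round(sample_rate)
  if (n <= win) stopf("end_of_test: need at least 1 s of data")
  dv <- volume[(win + 1):n] - volume[1:(n - win)]  # 1-s forward increments
  quiet <- dv < threshold
  # first index from which every later window is also quiet
  ok <- rev(cumprod(rev(quiet))) > 0
  if (!any(ok)) return(list(index = n, plateau_reached = FALSE))
  list(index = which(ok)[1], plateau_reached = TRUE)
}

#' Spirometry metrics of one maneuver
#'
#' Computes the standard forced-expiration metrics from a reconstructed
#' flow/volume pair and a corrected time zero: FEV1 is the volume between
#' `t0` and `t0 + 1` s (linear interpolation between samples), FVC is the
#' plateau volume (the cumulative volume at the end of the maneuver
#' segment), PEF the maximum flow, and FET is the expiratory time from `t0`
#' to the end of the maneuver segment (terminal sub-resolution flow cannot
#' be distinguished from zero, so the segment end marks the end of
#' detectable exhalation; the plateau time found by [end_of_test()] is
#' reported separately as `plateau_time`).
#'
#' @param flow Flow series, L/s.
#' @param volume Volume series, L.
#' @param t0 Corrected start time, s (on the same zero-based axis).
#' @param sample_rate Sampling rate, Hz.
#' @param bev Back-extrapolated volume, L (stored in the result).
#' @return An object of class `spirometry_metrics`: `fev1`, `fvc`, `pef`,
#'   `fev1_fvc_ratio`, `fet`, `bev`, `t0`, and the end-of-test flag
#'   `plateau_reached`.
#' @export
compute_metrics <- function(flow, volume, t0, sample_rate, bev = 0) {
  flow <- as.numeric(flow)
  n <- length(flow)
  t <- (seq_len(n) - 1) / sample_rate
  if (t0 < t[1] || t0 > t[n]) stopf("compute_metrics: t0 outside the segment")
  if (t[n] - t0 < 1)
    stopf("compute_metrics: segment shorter than 1 s after t0; FEV1 undefined")
  vol_at <- function(x) stats::approx(t, volume, xout = x, rule = 2)$y
  fev1 <- vol_at(t0 + 1) - vol_at(t0)
  eot <- end_of_test(volume, sample_rate)
  fvc <- volume[n]
  structure(list(fev1 = fev1, fvc = fvc, pef = max(flow),
                 fev1_fvc_ratio = fev1 / fvc,
                 fet = t[n] - t0, bev = bev, t0 = t0,
                 plateau_time = t[eot$index],
                 plateau_reached = eot$plateau_reached),
            class = "spirometry_metrics")
}

#' @export
print.spirometry_metrics <- function(x, ...) {
  cat(sprintf(
    "<spirometry_metrics> FEV1 %.3f L | FVC %.3f L | ratio %.3f | PEF %.2f L/s | FET %.2f s | BEV %.3f L\n",
    x$fev1, x$fvc, x$fev1_fvc_ratio, x$pef, x$fet, x$bev))
  invisible(x)
}

#' Analyse one maneuver segment
#'
#' Convenience wrapper: integrates volume, locates the back-extrapolated
#' time zero, computes metrics and attaches the extended acceptability
#' flags (BEV below `max(0.150 L, 5% FVC)`, FET >= 6 s, plateau reached).
#'
#' @param flow Flow series of the maneuver segment, L/s.
#' @param sample_rate Sampling rate, Hz.
#' @return A `spirometry_metrics` object with a `flags` list
#'   (`bev_ok`, `fet_ok`, `end_of_test_ok`).
#' @export
analyze_maneuver <- function(flow, sample_rate) {
  volume <- integrate_volume(flow, sample_rate)
  tz <- detect_time_zero(volume, flow, sample_rate)
  m <- compute_metrics(flow, volume, tz$t0, sample_rate, bev = tz$bev)
  m$flags <- list(bev_ok = m$bev < max(0.150, 0.05 * m$fvc),
                  fet_ok = m$fet >= 6,
                  end_of_test_ok = m$plateau_reached)
  m
}

#' Flow-volume loop (expiratory limb)
#'
#' Resamples the expiratory limb onto a uniform expired-volume grid for
#' plotting or CSV export.
#'
#' @param flow Flow series, L/s (nonnegative).
#' @param volume Volume series, L.
#' @param n_points Number of volume grid points.
#' @return `data.frame` with `volume` (L, nondecreasing) and `flow` (L/s).
#' @export
flow_volume_loop <- function(flow, volume, n_points = 200) {
  flow <- pmax(as.numeric(flow), 0)
  grid <- seq(0, max(volume), length.out = n_points)
  data.frame(volume = grid,
             flow = stats::approx(volume, flow, xout = grid, ties = "ordered",
                                  rule = 2)$y)
}

#' Analyse a full session trace
#'
#' Runs the complete spirometry pipeline on a [raw_trace()]: zero-offset
#' estimation from the rest window, dual-range flow reconstruction,
#' per-maneuver metric extraction over the annotated maneuver segments, and
#' session grading.
#'
#' @param trace A [raw_trace()] with `rest` and `maneuver` annotations.
#' @param cal A [sensor_calibration()].
#' @return List with `maneuvers` (list of `spirometry_metrics`), `report`
#'   (see [grade_session()]), `offsets`, and the fused `flow` series.
#' @export
analyze_session <- function(trace, cal = default_calibration()) {
  offsets <- estimate_zero_offset(trace)
  flow <- reconstruct_flow(trace, cal, offsets)
  ann <- trace$annotations
  manv <- ann[ann$label == "maneuver", , drop = FALSE]
  metrics <- vector("list", nrow(manv))
  for (i in seq_len(nrow(manv))) {
    idx <- trace$t >= manv$start_s[i] & trace$t <= manv$end_s[i]
    metrics[[i]] <- analyze_maneuver(flow[idx], trace$sample_rate)
  }
  list(maneuvers = metrics,
       report = if (length(metrics) >= 2) grade_session(metrics) else
         list(status = "grading-unavailable"),
       offsets = offsets, flow = flow)
}
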