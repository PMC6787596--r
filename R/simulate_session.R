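#' Raw multi-channel voltage trace
#'
#' The uniformly sampled record produced by the (virtual) device: two
#' differential-pressure channels, two gas channels, and segment
#' annotations.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param t Time vector, s (strictly increasing, uniform).
#' @param v_pressure_a,v_pressure_b,v_gas_no,v_gas_co Voltage series, V.
#' @param annotations `data.frame` with columns `label`, `start_s`, `end_s`.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(sample_rate, t, v_pressure_a, v_pressure_b,
                      v_gas_no, v_gas_co,
                      annotations = data.frame(label = character(),
                                               start_s = numeric(),
                                               end_s = numeric())) {
  n <- length(t)
  for (ch in list(v_pressure_a, v_pressure_b, v_gas_no, v_gas_co))
    if (length(ch) != n) stopf("raw_trace: all channels must match length(t) = %d", n)
  if (n > 1) {
    dts <- diff(t)
    if (any(dts <= 0)) stopf("raw_trace: t must be strictly increasing")
    if (max(abs(dts - 1 / sample_rate)) > 0.01 / sample_rate)
      stopf("raw_trace: t must be uniform at sample_rate (tolerance 1%% of the period)")
  }
  stopifnot(is.data.frame(annotations),
            all(c("label", "start_s", "end_s") %in% names(annotations)))
  structure(list(sample_rate = sample_rate, t = t,
                 v_pressure_a = v_pressure_a, v_pressure_b = v_pressure_b,
                 v_gas_no = v_gas_no, v_gas_co = v_gas_co,
                 annotations = annotations),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples @ %g Hz (%.1f s), %d annotated segments\n",
              length(x$t), x$sample_rate,
              if (length(x$t)) max(x$t) else 0, nrow(x$annotations)))
  if (nrow(x$annotations)) {
    a <- x$annotations
    cat(paste0("  ", a$label, ": ", sprintf("%.2f", a$start_s), "-",
               sprintf("%.2f", a$end_s), " s", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Session protocol script
#'
#' Timing and subject parameters for one simulated test session: 60 s of
#' tidal breathing (during which the gas channels are read), 5 s of rest
#' before the device signals, then the forced maneuvers.
#'
#' @param tidal_duration Tidal-breathing duration, s.
#' @param rest_duration Rest before the first maneuver, s.
#' @param n_maneuvers Number of forced maneuvers (>= 1).
#' @param gas_no_true True exhaled NO, ppb.
#' @param gas_co_true True exhaled CO, ppm.
#' @param gps Latitude/longitude tag, decimal degrees (metadata only).
#' @param subject_group `"control"`, `"asthma"` or `"COPD"`.
#' @param rng_seed Integer seed; the whole session is deterministic given it.
#' @return An object of class `session_script`.
#' @export
session_script <- function(tidal_duration = 60, rest_duration = 5,
                           n_maneuvers = 3, gas_no_true = 60,
                           gas_co_true = 3.04,
                           gps = c(lat = 38.5, lon = -121.7),
                           subject_group = c("control", "asthma", "COPD"),
                           rng_seed = 1L) {
  subject_group <- match.arg(subject_group)
  if (n_maneuvers < 1) stopf("session_script: n_maneuvers must be >= 1")
  if (gas_no_true < 0 || gas_co_true < 0)
    stopf("session_script: gas concentrations must be >= 0")
  if (tidal_duration < 0 || rest_duration < 1)
    stopf("session_script: durations invalid (rest must be >= 1 s)")
  structure(list(tidal_duration = tidal_duration,
                 rest_duration = rest_duration,
                 n_maneuvers = as.integer(n_maneuvers),
                 gas_no_true = gas_no_true, gas_co_true = gas_co_true,
                 gps = gps, subject_group = subject_group,
                 rng_seed = as.integer(rng_seed)),
            class = "session_script")
}

# Tidal breathing: 0.25 Hz sinusoid with ~0.5 L tidal volume.
# Half-cycle volume A/(pi*f) = V_T  =>  A = V_T * pi * f.
tidal_flow <- function(t_local, tidal_volume = 0.5, freq = 0.25) {
  tidal_volume * pi * freq * sin(2 * pi * freq * t_local)
}

#' Simulate a full breath-test session
#'
#' Assembles the physiological flow and gas time lines of one session --
#' tidal breathing, rest, then `n_maneuvers` forced expirations each
#' preceded by a deep inhalation and separated by recovery breathing -- and
#' passes them through the device forward model to produce a [raw_trace()].
#' Gas concentrations equilibrate with a short first-order time constant
#' after the subject engages the mouthpiece and are subject to slow random
#' baseline drift plus white noise. Deterministic given `rng_seed`.
#'
#' @param script A [session_script()].
#' @param cal A [sensor_calibration()] (its channel `noise_sd` values set
#'   the noise level; use [default_calibration()]`(noisy = FALSE)` for a
#'   noiseless session).
#' @param params A [maneuver_params()] object for the forced maneuvers;
#'   defaults to the phenotype preset matching `script$subject_group`.
#' @param maneuver_effects Optional numeric vector (length `n_maneuvers`) of
#'   multiplicative within-subject effort factors; drawn lognormal with 2%
#'   SD when `NULL`. Each maneuver's flow (hence FEV1/FVC/PEF) scales by its
#'   factor.
#' @param gas_drift_sd SD of the random linear baseline-drift slope, V/s.
#' @param gas_equilibration_tau First-order gas equilibration constant, s.
#' @param quantize Apply ADC quantization in the forward model?  Disable
#'   together with a noiseless calibration to simulate an ideal analog
#'   front end.
#' @return A list with `trace` (a [raw_trace()]) and `truth`, the ground
#'   truth: per-maneuver achieved metrics (`fev1`, `fvc`, `pef`, `fet`),
#'   the maneuver effort factors, and the true gas concentrations.
#' @export
make_session <- function(script, cal = default_calibration(), params = NULL,
                         maneuver_effects = NULL, gas_drift_sd = 2e-4,
                         gas_equilibration_tau = 2, quantize = TRUE) {
  stopifnot(inherits(script, "session_script"),
            inherits(cal, "sensor_calibration"))
  if (is.null(params)) {
    preset_name <- c(control = "healthy", asthma = "asthma", COPD = "COPD")
    params <- phenotype_presets()[[preset_name[[script$subject_group]]]]
  }
  stopifnot(inherits(params, "maneuver_params"))

  fs <- cal$sample_rate
  dt <- 1 / fs
  profile <- make_expiratory_flow(params, sample_rate = fs)

  with_seed(script$rng_seed, {
    nm <- script$n_maneuvers
    if (is.null(maneuver_effects))
      maneuver_effects <- stats::rlnorm(nm, meanlog = 0, sdlog = 0.02)
    stopifnot(length(maneuver_effects) == nm)

    inhale_dur <- 2
    recovery_dur <- 8
    tail_dur <- 3

    segs <- list(list(label = "tidal", dur = script$tidal_duration),
                 list(label = "rest", dur = script$rest_duration))
    for (i in seq_len(nm)) {
      segs <- c(segs, list(list(label = "inhalation", dur = inhale_dur),
                           list(label = "maneuver", dur = params$fet_total,
                                maneuver = i)))
      segs <- c(segs, list(list(label = if (i < nm) "recovery" else "tail",
                                dur = if (i < nm) recovery_dur else tail_dur)))
    }

    durs <- vapply(segs, `[[`, numeric(1), "dur")
    starts <- cumsum(c(0, durs[-length(durs)]))
    total <- sum(durs)
    n <- round(total * fs)
    t <- (seq_len(n) - 1) * dt

    flow <- numeric(n)
    ann <- data.frame(label = character(), start_s = numeric(),
                      end_s = numeric(), stringsAsFactors = FALSE)
    truth_man <- vector("list", nm)
    for (j in seq_along(segs)) {
      seg <- segs[[j]]
      idx <- which(t >= starts[j] - dt / 2 & t < starts[j] + seg$dur - dt / 2)
      tl <- t[idx] - starts[j]
      flow[idx] <- switch(seg$label,
        tidal = ,
        recovery = tidal_flow(tl),
        rest = ,
        tail = 0,
        inhalation = -pi * params$fvc_true / (2 * inhale_dur) *
          sin(pi * tl / inhale_dur),
        maneuver = {
          m <- maneuver_effects[seg$maneuver]
          truth_man[[seg$maneuver]] <- list(
            fev1 = m * profile$truth$fev1, fvc = m * profile$truth$fvc,
            pef = m * profile$truth$pef, fet = profile$truth$fet,
            effect = m)
          m * profile$flow[seq_along(idx)]
        })
      ann <- rbind(ann, data.frame(label = seg$label, start_s = starts[j],
                                   end_s = starts[j] + seg$dur))
    }

    # forward transduction: flow -> pressure -> voltage per channel
    va <- pressure_to_voltage(flow_to_pressure(flow, cal$pressure_a),
                              cal$pressure_a, noisy = TRUE,
                              quantize = quantize)
    vb <- pressure_to_voltage(flow_to_pressure(flow, cal$pressure_b),
                              cal$pressure_b, noisy = TRUE,
                              quantize = quantize)

    # gas concentrations: first-order equilibration toward the true values,
    # then constant; voltage-domain drift and noise on top
    equil <- 1 - exp(-t / gas_equilibration_tau)
    conc_no <- script$gas_no_true / 1000 * equil  # ppb -> ppm
    conc_co <- script$gas_co_true * equil
    drift_no <- stats::rnorm(1, 0, gas_drift_sd) * t
    drift_co <- stats::rnorm(1, 0, gas_drift_sd) * t
    step <- adc_step(cal$pressure_a)  # ADC shared across channels
    gas_channel <- function(conc, spec, drift) {
      v <- spec$v_baseline + spec$sensitivity * conc + drift
      if (spec$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
      v <- pmin(pmax(v, 0), cal$pressure_a$v_ref)
      if (quantize) v <- round(v / step) * step
      v
    }
    vno <- gas_channel(conc_no, cal$gas_no, drift_no)
    vco <- gas_channel(conc_co, cal$gas_co, drift_co)

    trace <- raw_trace(fs, t, va, vb, vno, vco, ann)
    truth <- list(maneuvers = truth_man, maneuver_effects = maneuver_effects,
                  gas_no_true_ppb = script$gas_no_true,
                  gas_co_true_ppm = script$gas_co_true,
                  subject_group = script$subject_group,
                  params = params, rng_seed = script$rng_seed)
    list(trace = trace, truth = truth)
  })
}
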