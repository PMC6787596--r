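# Flow reconstruction, volume integration, time-zero correction, metrics.

test_that("zero-offset estimation recovers channel offsets", {
  cal <- quiet_cal()
  trace <- flow_to_trace(numeric(300))
  off <- estimate_zero_offset(trace)
  step <- adc_step(cal$pressure_a)
  expect_lt(abs(off[["v_pressure_a"]] - cal$pressure_a$v_offset), step)
  expect_lt(abs(off[["v_pressure_b"]] - cal$pressure_b$v_offset), step)
  # adding 0.1 V to a channel shifts its estimated offset by exactly 0.1 V
  tr2 <- trace
  tr2$v_pressure_a <- tr2$v_pressure_a + 0.1
  off2 <- estimate_zero_offset(tr2)
  expect_equal(off2[["v_pressure_a"]] - off[["v_pressure_a"]], 0.1)
  expect_equal(off2[["v_pressure_b"]], off[["v_pressure_b"]])
})

test_that("offset estimate under symmetric noise stays within the Monte-Carlo bound", {
  cal <- quiet_cal()
  n <- 500
  set.seed(88)
  noise_sd <- 0.01
  v <- cal$pressure_a$v_offset + rnorm(n, 0, noise_sd)  # unquantized channel
  t <- (seq_len(n) - 1) / 100
  tr <- raw_trace(100, t, v, v, v, v,
                  data.frame(label = "rest", start_s = 0, end_s = t[n]))
  off <- estimate_zero_offset(tr)
  expect_lt(abs(off[["v_pressure_a"]] - cal$pressure_a$v_offset),
            3 * noise_sd / sqrt(n))
})

test_that("missing rest annotation falls back to the first two seconds with a warning", {
  tr <- flow_to_trace(numeric(300))
  tr$annotations <- tr$annotations[tr$annotations$label != "rest", ]
  expect_warning(off <- estimate_zero_offset(tr), "first 2 s")
  expect_lt(abs(off[["v_pressure_a"]] - 0.2), adc_step(quiet_cal()$pressure_a))
})

test_that("reconstruction recovers PEF, survives zero traces, and is span-invariant", {
  # noiseless maneuver -> PEF within 1%
  prof <- make_expiratory_flow(phenotype_presets()$healthy, 100)
  tr <- flow_to_trace(prof$flow, quantize = FALSE)
  flow <- reconstruct_flow(tr, quiet_cal())
  expect_rel_error(max(flow), prof$truth$pef, 0.01)
  # all-zero voltages -> all-zero flow, no exception
  n <- 400
  tr0 <- raw_trace(100, (0:(n - 1)) / 100, numeric(n), numeric(n), numeric(n),
                   numeric(n),
                   data.frame(label = "rest", start_s = 0, end_s = 2))
  expect_true(all(reconstruct_flow(tr0, quiet_cal()) == 0))
  # doubling v_span and the voltage excursions consistently changes nothing
  cal2 <- quiet_cal()
  cal2$pressure_a$v_span <- cal2$pressure_a$v_span * 2
  cal2$pressure_b$v_span <- cal2$pressure_b$v_span * 2
  # the doubled-span device needs ADC headroom so nothing clips
  cal2$pressure_a$v_ref <- 10
  cal2$pressure_b$v_ref <- 10
  scale_channel <- function(v, off) off + 2 * (v - off)
  tr2 <- tr
  tr2$v_pressure_a <- scale_channel(tr$v_pressure_a, 0.2)
  tr2$v_pressure_b <- scale_channel(tr$v_pressure_b, 0.2)
  expect_equal(as.numeric(reconstruct_flow(tr2, cal2)),
               as.numeric(flow), tolerance = 1e-9)
})

test_that("volume integration is exact for constants and ramps", {
  fs <- 100
  expect_equal(integrate_volume(rep(0.5, 4 * fs + 1), fs)[4 * fs + 1], 2.0)
  ramp <- seq(0, 1, length.out = 2 * fs + 1)
  expect_equal(integrate_volume(ramp, fs)[2 * fs + 1], 1.0)
  # random nonnegative flow vs an independent per-segment area oracle
  set.seed(12)
  y <- runif(200)
  v <- integrate_volume(y, fs)
  oracle <- 0
  for (i in seq_len(199)) oracle <- oracle + (y[i] + y[i + 1]) / (2 * fs)
  expect_lt(abs(v[200] - oracle), 1e-12)
  expect_true(all(diff(v) >= 0))
})

test_that("back-extrapolation matches the symbolic tangent construction", {
  fs <- 100
  # instantaneous rise to constant flow: tangent passes through the origin
  flow <- rep(1, 3 * fs)
  vol <- integrate_volume(flow, fs)
  tz <- detect_time_zero(vol, flow, fs)
  expect_equal(tz$t0, 0)
  expect_equal(tz$bev, 0)
  # linear rise a*t to T, then constant: tangent at peak flow a*T touches the
  # parabola a t^2/2, giving t0 = T/2 and bev = a T^2 / 8 exactly
  a <- 2; T <- 0.5
  t <- (0:(3 * fs)) / fs
  flow <- pmin(a * t, a * T)
  vol <- integrate_volume(flow, fs)
  tz <- detect_time_zero(vol, flow, fs)
  expect_equal(tz$t0, T / 2, tolerance = 1e-6)
  expect_equal(tz$bev, a * T^2 / 8, tolerance = 1e-6)
  # translation equivariance: prepending 0.5 s of zeros shifts t0 only
  flow_sh <- c(numeric(fs / 2), flow)
  tz_sh <- detect_time_zero(integrate_volume(flow_sh, fs), flow_sh, fs)
  expect_equal(tz_sh$t0, tz$t0 + 0.5, tolerance = 1e-9)
  expect_equal(tz_sh$bev, tz$bev, tolerance = 1e-9)
  # no expiratory rise at all -> unusable maneuver
  expect_error(detect_time_zero(numeric(300), numeric(300), fs), "unusable")
})

test_that("metrics on a constant-flow segment match hand values", {
  fs <- 100
  flow <- rep(0.5, 4 * fs + 1)
  vol <- integrate_volume(flow, fs)
  m <- compute_metrics(flow, vol, t0 = 0, sample_rate = fs)
  expect_equal(m$fev1, 0.5)
  expect_equal(m$fvc, 2.0)
  expect_equal(m$fev1_fvc_ratio, 0.25)
  expect_equal(m$pef, 0.5)
  expect_false(m$plateau_reached)  # constant flow never plateaus
  expect_error(compute_metrics(flow[1:50], vol[1:50], 0, fs), "1 s")
})

test_that("noiseless end-to-end analysis recovers the simulated metrics within 1%", {
  for (preset in names(phenotype_presets())) {
    p <- phenotype_presets()[[preset]]
    ses <- maneuver_session(p, seed = 2, noisy = FALSE, quantize = FALSE)
    res <- analyze_session(ses$trace, quiet_cal())
    m <- res$maneuvers[[1]]
    tr <- ses$truth$maneuvers[[1]]
    expect_rel_error(m$fev1, tr$fev1, 0.01)
    expect_rel_error(m$fvc, tr$fvc, 0.01)
    expect_rel_error(m$pef, tr$pef, 0.01)
    expect_true(m$flags$bev_ok)
    expect_true(m$flags$fet_ok)
  }
})

test_that("asthma preset reproduces the expected FEV1/FVC ratio", {
  # group-mean asthma values give a ratio of 2.37/3.02 ~ 0.785
  ses <- maneuver_session(phenotype_presets()$asthma, seed = 4,
                          noisy = FALSE, quantize = FALSE)
  res <- analyze_session(ses$trace, quiet_cal())
  expect_rel_error(res$maneuvers[[1]]$fev1_fvc_ratio, 2.37 / 3.02, 0.02)
})

test_that("end-of-test detection matches the analytic plateau time", {
  fs <- 100
  # exponential decay: trailing 1-s volume falls below 0.025 L at
  # t* = tau * log(A tau (1 - exp(-1/tau)) / 0.025)
  A <- 2; tau <- 0.5
  t <- (0:(10 * fs)) / fs
  flow <- A * exp(-t / tau)
  eot <- end_of_test(integrate_volume(flow, fs), fs)
  t_star <- tau * log(A * tau * (1 - exp(-1 / tau)) / 0.025)
  expect_true(eot$plateau_reached)
  expect_lt(abs(t[eot$index] - t_star), 1 / fs + 1e-9)
  # flow hitting exact zero at 6 s: detected end of test is at or before 6 s
  flow6 <- pmax(1 - t / 6, 0)
  eot6 <- end_of_test(integrate_volume(flow6, fs), fs)
  expect_lte(t[eot6$index], 6 + 1 / fs)
  # never-decaying flow: no plateau
  eotc <- end_of_test(integrate_volume(rep(1, 8 * fs), fs), fs)
  expect_false(eotc$plateau_reached)
})

test_that("time-zero correction does not inflate FEV1 on slow-start maneuvers", {
  fs <- 100
  t <- (0:(6 * fs)) / fs
  # 0.3 s of slow leak before an abrupt blast with fast decay
  flow <- ifelse(t < 0.3, 0.3, 6 * exp(-(t - 0.3) / 0.25))
  vol <- integrate_volume(flow, fs)
  tz <- detect_time_zero(vol, flow, fs)
  expect_gt(tz$bev, 0)
  fev1_t0 <- compute_metrics(flow, vol, tz$t0, fs)$fev1
  fev1_naive <- compute_metrics(flow, vol, 0, fs)$fev1
  expect_lte(fev1_t0, fev1_naive)
})

test_that("flow-volume loop export is monotone in volume and nonnegative in flow", {
  prof <- make_expiratory_flow(phenotype_presets()$asthma, 100)
  loop <- flow_volume_loop(prof$flow, integrate_volume(prof$flow, 100))
  expect_true(all(diff(loop$volume) >= 0))
  expect_true(all(loop$flow >= 0))
})
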