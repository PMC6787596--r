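# Group-level spirometry distributions (L): means and SDs per subject group.
cohort_group_stats <- function() {
  list(control = list(fev1_mean = 3.74, fev1_sd = 0.54,
                      fvc_mean = 4.42, fvc_sd = 0.66,
                      shape = 1.2, fet = 6.5),
       asthma = list(fev1_mean = 2.37, fev1_sd = 1.10,
                     fvc_mean = 3.02, fvc_sd = 1.24,
                     shape = 0.9, fet = 7),
       COPD = list(fev1_mean = 1.06, fev1_sd = 0.55,
                   fvc_mean = 2.05, fvc_sd = 0.70,
                   shape = 0.6, fet = 10))
}

# Lognormal parameters matching a target mean and SD exactly.
lnorm_pars <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Draw per-subject true spirometry values for a group
#'
#' FVC is drawn lognormal with the group's mean and SD (positive support,
#' exact first two moments); the FEV1/FVC ratio is drawn normal around the
#' group's mean ratio (SD 0.06, clamped to physiological bounds) and FEV1 is
#' their product, so group mean FEV1 matches the configured value.
#'
#' @param n Number of subjects.
#' @param group Group name.
#' @return `data.frame` with `fev1`, `fvc`, `ratio`.
#' @keywords internal
draw_subject_truth <- function(n, group) {
  gs <- cohort_group_stats()[[group]]
  lp <- lnorm_pars(gs$fvc_mean, gs$fvc_sd)
  fvc <- stats::rlnorm(n, lp["meanlog"], lp["sdlog"])
  r0 <- gs$fev1_mean / gs$fvc_mean
  ratio <- pmin(pmax(stats::rnorm(n, r0, 0.06), 0.25), 0.92)
  data.frame(fev1 = ratio * fvc, fvc = fvc, ratio = ratio)
}

#' Simulate a paired-device benchmark cohort
#'
#' Emulates the benchmark design: each subject performs `n_maneuvers`
#' forced maneuvers on each of two virtual devices.  Per-subject true
#' FEV1/FVC are drawn from group-anchored distributions; within-subject
#' maneuver-to-maneuver effort factors (lognormal, 2% SD) are drawn per
#' maneuver index and shared across the two devices (paired-effort design,
#' matching the per-maneuver pairing convention of the agreement module);
#' each device gets independent sensor noise and its own slightly perturbed
#' calibration (lognormal jitter on the orifice coefficients).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param group_mix Named numeric vector of group weights over
#'   `control`/`asthma`/`COPD` (normalised internally).
#' @param seed Integer master seed; all draws derive from it.
#' @param n_maneuvers Maneuvers per device per subject.
#' @param cal Base [sensor_calibration()].
#' @param cal_jitter_sd SD of the lognormal per-device jitter on the
#'   orifice coefficients (0 disables).
#' @param quantize Apply ADC quantization in the forward model?
#' @param noisy Simulate sensor noise?
#' @param tidal_duration,rest_duration Session timing, s; the spirometry
#'   benchmark does not use the tidal window, so a short tidal phase speeds
#'   up large cohorts without changing the maneuvers.
#' @param generate_sessions If `FALSE`, only the per-subject ground truth is
#'   drawn (no traces), for studying the cohort distributions themselves.
#' @return A list of subjects; each has `subject_id`, `group`, `truth`
#'   (true fev1/fvc/ratio and per-maneuver effects) and `sessions`, a list
#'   of two `make_session()` results named `device_a` and `device_b`.
#' @export
make_cohort <- function(n_subjects, group_mix = c(control = 1, asthma = 1,
                                                  COPD = 1),
                        seed = 1L, n_maneuvers = 3,
                        cal = default_calibration(),
                        cal_jitter_sd = 0.005, noisy = TRUE, quantize = TRUE,
                        tidal_duration = 10, rest_duration = 5,
                        generate_sessions = TRUE) {
  if (n_subjects < 2) stopf("make_cohort: n_subjects must be >= 2")
  groups <- c("control", "asthma", "COPD")
  mix <- rep(0, 3); names(mix) <- groups
  mix[names(group_mix)] <- group_mix
  if (sum(mix) <= 0) stopf("make_cohort: group_mix must have positive total weight")
  mix <- mix / sum(mix)
  if (!noisy) cal <- strip_noise(cal)

  with_seed(seed, {
    grp <- sample(groups, n_subjects, replace = TRUE, prob = mix)
    subjects <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      tr <- draw_subject_truth(1, grp[i])
      gs <- cohort_group_stats()[[grp[i]]]
      pars <- maneuver_params(fev1_true = tr$fev1, fvc_true = tr$fvc,
                              pef_true = 2.2 * tr$fev1 + 0.5,
                              rise_time = 0.05, decay_shape = gs$shape,
                              fet_total = gs$fet,
                              phenotype = if (grp[i] == "control") "healthy"
                                          else grp[i])
      effects <- stats::rlnorm(n_maneuvers, 0, 0.02)
      dev_seeds <- sample.int(2147483646, 2)
      sessions <- NULL
      if (generate_sessions) {
        sessions <- list()
        for (d in 1:2) {
          # the device's physical orifice coefficients are perturbed, but the
          # analysis side only ever knows the nominal profile
          cal_d <- if (cal_jitter_sd > 0)
            jitter_calibration(cal, cal_jitter_sd) else cal
          sc <- session_script(tidal_duration = tidal_duration,
                               rest_duration = rest_duration,
                               n_maneuvers = n_maneuvers,
                               subject_group = grp[i],
                               rng_seed = dev_seeds[d])
          sessions[[c("device_a", "device_b")[d]]] <-
            make_session(sc, cal = cal_d, params = pars,
                         maneuver_effects = effects, quantize = quantize)
          sessions[[c("device_a", "device_b")[d]]]$true_calibration <- cal_d
          sessions[[c("device_a", "device_b")[d]]]$nominal_calibration <- cal
        }
      }
      subjects[[i]] <- list(subject_id = sprintf("S%03d", i), group = grp[i],
                            truth = c(as.list(tr), list(effects = effects)),
                            params = pars, sessions = sessions)
    }
    subjects
  })
}

# Zero all channel noise in a calibration.
strip_noise <- function(cal) {
  for (ch in c("pressure_a", "pressure_b", "gas_no", "gas_co"))
    cal[[ch]]$noise_sd <- 0
  cal
}

# Perturb the orifice coefficients by a lognormal factor (draws from the
# current RNG stream).
jitter_calibration <- function(cal, sd) {
  cal$pressure_a$orifice_coeff_k <-
    cal$pressure_a$orifice_coeff_k * stats::rlnorm(1, 0, sd)
  cal$pressure_b$orifice_coeff_k <-
    cal$pressure_b$orifice_coeff_k * stats::rlnorm(1, 0, sd)
  cal
}
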