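#' Forced-maneuver waveform parameters
#'
#' Target metrics and shape parameters for one simulated forced expiratory
#' maneuver: a linear rise to peak flow followed by a generalized
#' exponential decay whose scale and shape are solved so that the volume in
#' the first second equals `fev1_true` and the total exhaled volume equals
#' `fvc_true`.
#'
#' @param fev1_true Target FEV1, L (volume in the first second, timed from
#'   maneuver start).
#' @param fvc_true Target FVC, L (total exhaled volume over `fet_total`).
#' @param pef_true Target peak expiratory flow, L/s.
#' @param rise_time Time from start to peak flow, s (default 0.05, a typical
#'   time-to-PEF).
#' @param decay_shape Concavity parameter of the decay; values >= 1 are
#'   exponential-like (normal emptying), values < 1 give the scooped,
#'   long-tailed decay of obstructive disease. Used to initialise the shape
#'   solve, and thereby controls the branch the solver converges to.
#' @param fet_total Total forced expiratory time, s (>= 6).
#' @param phenotype Label: `"healthy"`, `"asthma"` or `"COPD"`.
#' @return An object of class `maneuver_params`.
#' @export
maneuver_params <- function(fev1_true, fvc_true, pef_true, rise_time = 0.05,
                            decay_shape = 1, fet_total = 6,
                            phenotype = c("healthy", "asthma", "COPD")) {
  phenotype <- match.arg(phenotype)
  if (!(fev1_true > 0 && fev1_true <= fvc_true))
    stopf("maneuver_params: need 0 < fev1_true <= fvc_true")
  if (fet_total < 6) stopf("maneuver_params: fet_total must be >= 6 s")
  if (pef_true < fvc_true / fet_total)
    stopf("maneuver_params: pef_true must be >= fvc_true / fet_total")
  if (rise_time < 0 || rise_time >= 1)
    stopf("maneuver_params: rise_time must be in [0, 1)")
  if (decay_shape <= 0) stopf("maneuver_params: decay_shape must be > 0")
  structure(list(fev1_true = fev1_true, fvc_true = fvc_true,
                 pef_true = pef_true, rise_time = rise_time,
                 decay_shape = decay_shape, fet_total = fet_total,
                 phenotype = phenotype),
            class = "maneuver_params")
}

#' Phenotype presets for the maneuver generator
#'
#' Default maneuver parameters per subject group.  FEV1 and FVC are anchored
#' to the cohort group means (healthy 3.74/4.42 L, asthma 2.37/3.02 L, COPD
#' 1.06/2.05 L); peak flows and decay shapes are chosen to give the
#' characteristic loop shapes (brisk near-exponential emptying when healthy,
#' progressively scooped decay with obstruction).
#'
#' @return Named list of [maneuver_params()] objects.
#' @export
phenotype_presets <- function() {
  list(
    healthy = maneuver_params(3.74, 4.42, pef_true = 8.5, rise_time = 0.05,
                              decay_shape = 1.2, fet_total = 6.5,
                              phenotype = "healthy"),
    asthma = maneuver_params(2.37, 3.02, pef_true = 6.0, rise_time = 0.05,
                             decay_shape = 0.9, fet_total = 7,
                             phenotype = "asthma"),
    COPD = maneuver_params(1.06, 2.05, pef_true = 3.2, rise_time = 0.05,
                           decay_shape = 0.6, fet_total = 10,
                           phenotype = "COPD")
  )
}

# Closed-form integral of the decay branch: int_0^T exp(-(u/tau)^s) du.
# Substituting x = (u/tau)^s turns it into a regularized lower incomplete
# gamma: tau * Gamma(1 + 1/s) * P(1/s, (T/tau)^s).
decay_integral <- function(T, tau, s) {
  if (T <= 0) return(0)
  tau * gamma(1 + 1 / s) * stats::pgamma((T / tau)^s, shape = 1 / s)
}

#' Generate a forced expiratory flow profile
#'
#' Builds the piecewise maneuver waveform: linear rise from zero to
#' `pef_true` over `rise_time`, then the generalized exponential decay
#' `Q(t) = PEF * exp(-(((t - rise_time) / tau))^shape)` truncated at
#' `fet_total`. The decay scale `tau` and shape are solved numerically
#' (initialised at `decay_shape`) so that the integral over the first second
#' matches `fev1_true` and the total integral matches `fvc_true`, each to
#' within 0.5%; the exact achieved integrals are returned as ground truth.
#'
#' @param params A [maneuver_params()] object.
#' @param sample_rate Sampling rate, Hz.
#' @return A list with `t` (s), `flow` (L/s), and `truth`, a list holding
#'   the achieved `fev1`, `fvc` (closed-form integrals of the realised
#'   waveform), `pef` (maximum of the series), `fet`, and the solved decay
#'   `tau` and `shape`.
#' @export
make_expiratory_flow <- function(params, sample_rate = 100) {
  stopifnot(inherits(params, "maneuver_params"))
  pef <- params$pef_true; tr <- params$rise_time
  fev1 <- params$fev1_true; fvc <- params$fvc_true; fet <- params$fet_total
  rise_area <- pef * tr / 2

  if (fev1 >= fvc)
    stopf("make_expiratory_flow: infeasible parameters: fev1_true must be strictly below fvc_true (a smooth decay keeps exhaling after 1 s)")
  if (rise_area >= fev1)
    stopf("make_expiratory_flow: infeasible parameters: rise-phase volume pef*rise_time/2 = %.3f L already exceeds fev1_true", rise_area)
  if (fev1 > rise_area + pef * (1 - tr))
    stopf("make_expiratory_flow: infeasible parameters: fev1_true exceeds the maximum volume pef_true can deliver in 1 s")
  if (fvc > rise_area + pef * (fet - tr))
    stopf("make_expiratory_flow: infeasible parameters: fvc_true exceeds the maximum volume pef_true can deliver in fet_total")

  t1 <- 1 - tr          # decay time covered by the first second
  tend <- fet - tr      # decay time covered by the whole maneuver
  target_fev1 <- fev1 - rise_area
  target_fvc <- fvc - rise_area

  resid <- function(par) {
    tau <- exp(par[1]); s <- exp(par[2])
    c((pef * decay_integral(t1, tau, s) - target_fev1) / target_fev1,
      (pef * decay_integral(tend, tau, s) - target_fvc) / target_fvc)
  }
  obj <- function(par) sum(resid(par)^2)

  s0 <- params$decay_shape
  tau0 <- max(target_fvc / (pef * gamma(1 + 1 / s0)), 1e-3)
  fit <- stats::optim(c(log(tau0), log(s0)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  r <- resid(fit$par)
  if (max(abs(r)) > 0.005) {
    worst <- if (abs(r[1]) >= abs(r[2])) "fev1_true" else "fvc_true"
    stopf("make_expiratory_flow: infeasible parameters: could not match %s within 0.5%% (relative residuals %.3g, %.3g) for the given pef/rise/fet",
          worst, r[1], r[2])
  }
  tau <- exp(fit$par[1]); s <- exp(fit$par[2])

  tt <- seq(0, fet, by = 1 / sample_rate)
  flow <- pef * exp(-(pmax(tt - tr, 0) / tau)^s)
  if (tr > 0) {
    rise <- tt < tr
    flow[rise] <- tt[rise] / tr * pef
  }
  truth <- list(
    fev1 = rise_area + pef * decay_integral(t1, tau, s),
    fvc = rise_area + pef * decay_integral(tend, tau, s),
    pef = max(flow),
    fet = fet,
    tau = tau,
    shape = s
  )
  list(t = tt, flow = flow, truth = truth, params = params,
       sample_rate = sample_rate)
}
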