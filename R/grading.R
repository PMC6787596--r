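#' Grade a session's maneuvers (acceptability and repeatability)
#'
#' Applies the session-level repeatability rule: the two largest FEV1
#' values must agree within 0.150 L, and likewise the two largest FVC
#' values. Reports the best values (maximum FEV1 and maximum FVC, possibly
#' from different maneuvers, the standard convention) with the ratio taken
#' from the maneuver with the largest FEV1 + FVC sum, and counts maneuvers
#' passing the extended per-maneuver acceptability flags (BEV, FET,
#' end-of-test) when those flags are present.
#'
#' @param metrics_list List of `spirometry_metrics` (or any lists carrying
#'   at least `fev1` and `fvc`).
#' @param repeatability_limit Agreement limit for the two largest values, L.
#' @return List of class `acceptability_report`: `status` (`"graded"` or
#'   `"grading-unavailable"`), `session_repeatable_fev1`,
#'   `session_repeatable_fvc`, `repeatable` (both), `n_acceptable`,
#'   `maneuver_flags` and `best` (`fev1`, `fvc`, `fev1_fvc_ratio`).
#' @export
grade_session <- function(metrics_list, repeatability_limit = 0.150) {
  if (length(metrics_list) < 2)
    return(structure(list(status = "grading-unavailable",
                          reason = "fewer than 2 maneuvers"),
                     class = "acceptability_report"))
  fev1 <- vapply(metrics_list, function(m) m$fev1, numeric(1))
  fvc <- vapply(metrics_list, function(m) m$fvc, numeric(1))
  s_fev1 <- sort(fev1, decreasing = TRUE)
  s_fvc <- sort(fvc, decreasing = TRUE)
  # epsilon guard so a difference that is exactly at the limit in exact
  # arithmetic (e.g. 2.45 - 2.30) is not failed by binary rounding
  eps <- 1e-9
  rep_fev1 <- (s_fev1[1] - s_fev1[2]) <= repeatability_limit + eps
  rep_fvc <- (s_fvc[1] - s_fvc[2]) <= repeatability_limit + eps
  flags <- lapply(metrics_list, function(m)
    if (is.null(m$flags)) list(bev_ok = NA, fet_ok = NA, end_of_test_ok = NA)
    else m$flags)
  acc <- vapply(flags, function(f)
    isTRUE(f$bev_ok) && isTRUE(f$fet_ok) && isTRUE(f$end_of_test_ok),
    logical(1))
  ibest <- which.max(fev1 + fvc)
  structure(list(status = "graded",
                 session_repeatable_fev1 = rep_fev1,
                 session_repeatable_fvc = rep_fvc,
                 repeatable = rep_fev1 && rep_fvc,
                 n_acceptable = sum(acc),
                 maneuver_flags = flags,
                 best = list(fev1 = max(fev1), fvc = max(fvc),
                             fev1_fvc_ratio = fev1[ibest] / fvc[ibest])),
            class = "acceptability_report")
}

#' @export
print.acceptability_report <- function(x, ...) {
  if (x$status != "graded") {
    cat("<acceptability_report> grading unavailable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<acceptability_report> repeatable FEV1: %s | repeatable FVC: %s | acceptable maneuvers: %d\n",
    x$session_repeatable_fev1, x$session_repeatable_fvc, x$n_acceptable))
  cat(sprintf("  best FEV1 %.3f L, best FVC %.3f L, ratio %.3f\n",
              x$best$fev1, x$best$fvc, x$best$fev1_fvc_ratio))
  invisible(x)
}

#' Percent of predicted value
#'
#' Computes `100 * measured / predicted` using a pluggable registry of
#' reference equations. The registry maps a demographic stratum to a
#' function `function(demographics) -> list(fev1 = , fvc = )` returning
#' predicted values in litres; deriving reference equations is out of scope
#' here, so only the lookup-and-ratio plumbing is provided.
#'
#' @param metrics A `spirometry_metrics` object (or list with `fev1`,
#'   `fvc`).
#' @param demographics List with at least `sex` and any fields the
#'   registry's equations use (`age`, `height_cm`, ...).
#' @param registry Named list of prediction functions keyed by stratum
#'   (e.g. `"male"`, `"female"`), or a single function under `"default"`.
#' @return Named list `fev1_percent_predicted`, `fvc_percent_predicted`.
#' @export
percent_predicted <- function(metrics, demographics, registry) {
  key <- demographics$sex
  fn <- registry[[key %||% "default"]] %||% registry[["default"]]
  if (is.null(fn))
    stopf("percent_predicted: no reference equation for stratum '%s'",
          key %||% "default")
  pred <- fn(demographics)
  if (!all(c("fev1", "fvc") %in% names(pred)) ||
      !is_scalar_number(pred$fev1) || !is_scalar_number(pred$fvc) ||
      pred$fev1 <= 0 || pred$fvc <= 0)
    stopf("percent_predicted: registry returned invalid predictions for stratum '%s'",
          key %||% "default")
  list(fev1_percent_predicted = 100 * metrics$fev1 / pred$fev1,
       fvc_percent_predicted = 100 * metrics$fvc / pred$fvc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
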