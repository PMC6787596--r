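#' Pearson correlation between paired device readings
#'
#' Standard product-moment correlation with a two-sided p-value from the
#' t-transform on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors (n >= 3, nonzero variance).
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("pearson: need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("pearson: undefined correlation (zero variance)")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences `a - b` summarised by their mean (bias) and 95%
#' limits of agreement, `bias +/- 1.96 * SD` of the differences (SD with
#' n - 1 denominator; the 1.96 normal multiplier is the conventional
#' choice and is configurable).
#'
#' @param a,b Paired measurements from the two devices.
#' @param multiplier Limits-of-agreement multiplier.
#' @return List of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n`, and `points` (`data.frame` of per-pair `mean` and
#'   `diff`).
#' @export
bland_altman <- function(a, b, multiplier = 1.96) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stopf("bland_altman: need at least 2 complete pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - multiplier * s,
                 loa_high = bias + multiplier * s, sd_diff = s,
                 n = length(d),
                 points = data.frame(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4f, 95%% LoA [%.4f, %.4f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Two-factor analysis of variance (device and health state)
#'
#' Fixed-effects two-way ANOVA with interaction, using type-II sums of
#' squares so unbalanced group sizes are handled sensibly. Every
#' device-by-group cell must contain at least one observation. When one of
#' the two factors is constant the design degenerates to a one-way ANOVA on
#' the other factor (in which case the two-level F statistic equals the
#' squared two-sample t statistic).
#'
#' @param values Numeric response (e.g. FEV1 in L).
#' @param device_factor Factor/character: which device produced the value.
#' @param group_factor Factor/character: health state.
#' @return `data.frame` with rows for each factor, the interaction, and
#'   residuals; columns `term`, `sum_sq`, `df`, `f`, `p`.
#' @export
two_factor_anova <- function(values, device_factor, group_factor) {
  device_factor <- factor(device_factor)
  group_factor <- factor(group_factor)
  if (nlevels(device_factor) < 2 && nlevels(group_factor) < 2)
    stopf("two_factor_anova: at least one factor needs >= 2 levels")
  # degenerate design: one factor constant -> one-way ANOVA on the other
  # (this is the case in which the device F statistic equals t^2)
  if (nlevels(group_factor) < 2 || nlevels(device_factor) < 2) {
    fac <- if (nlevels(device_factor) >= 2) device_factor else group_factor
    nm <- if (nlevels(device_factor) >= 2) "device" else "group"
    a <- stats::anova(stats::lm(values ~ fac))
    return(data.frame(term = c(nm, "residuals"),
                      sum_sq = a[["Sum Sq"]], df = a[["Df"]],
                      f = a[["F value"]], p = a[["Pr(>F)"]]))
  }
  cells <- table(device_factor, group_factor)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stopf("two_factor_anova: empty cell (device = %s, group = %s)",
          rownames(cells)[empty[1]], colnames(cells)[empty[2]])
  }
  if (stats::var(values) == 0) {
    terms <- c("device", "group", "device:group", "residuals")
    return(data.frame(term = terms, sum_sq = 0,
                      df = c(nlevels(device_factor) - 1L,
                             nlevels(group_factor) - 1L,
                             (nlevels(device_factor) - 1L) *
                               (nlevels(group_factor) - 1L),
                             length(values) - nlevels(device_factor) *
                               nlevels(group_factor)),
                      f = c(0, 0, 0, NA), p = c(1, 1, 1, NA)))
  }
  dat <- data.frame(value = values, device = device_factor,
                    group = group_factor)
  fit <- stats::lm(value ~ device * group, data = dat)
  tab <- car::Anova(fit, type = 2)
  data.frame(term = c("device", "group", "device:group", "residuals"),
             sum_sq = tab[["Sum Sq"]], df = tab[["Df"]],
             f = tab[["F value"]], p = tab[["Pr(>F)"]])
}

#' Correlations between repeated readings
#'
#' Pearson correlation across subjects for each pair of reading indices
#' (reading 1 vs 2, 1 vs 3, 2 vs 3 for three readings), with pairwise
#' deletion of missing readings.
#'
#' @param readings Numeric matrix, subjects in rows, reading index in
#'   columns (>= 2 columns).
#' @return `data.frame` with `pair`, `r`, `p`, `n`, `available`.
#' @export
repeated_reading_correlation <- function(readings) {
  readings <- as.matrix(readings)
  if (ncol(readings) < 2)
    stopf("repeated_reading_correlation: need >= 2 reading columns")
  pairs <- utils::combn(ncol(readings), 2)
  out <- data.frame(pair = character(), r = numeric(), p = numeric(),
                    n = integer(), available = logical())
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ok <- stats::complete.cases(readings[, i1], readings[, i2])
    row <- data.frame(pair = sprintf("%d-%d", i1, i2), r = NA_real_,
                      p = NA_real_, n = sum(ok), available = FALSE)
    if (sum(ok) >= 3 && stats::var(readings[ok, i1]) > 0 &&
        stats::var(readings[ok, i2]) > 0) {
      pr <- pearson(readings[ok, i1], readings[ok, i2])
      row$r <- pr$r; row$p <- pr$p; row$available <- TRUE
    }
    out <- rbind(out, row)
  }
  out
}

#' Paired-device agreement report for one metric
#'
#' Bundles the benchmark statistics for one metric from a long-format
#' paired table: Pearson correlation, Bland-Altman bias and limits of
#' agreement, the two-factor (device and health state) ANOVA, and
#' per-device mean and SEM.
#'
#' @param paired `data.frame` with columns `subject_id`, `group`,
#'   `maneuver_index`, `value_device_a`, `value_device_b` (pairs with a
#'   missing side are excluded and counted).
#' @param metric_name Metric label carried into the result.
#' @param anova_mode `"per_maneuver"` (default) uses every maneuver pair as
#'   an observation; `"per_subject"` averages maneuvers within subject
#'   first.
#' @return List of class `agreement_result`: `metric`, `n_pairs`,
#'   `n_excluded`, `pearson_r`, `pearson_p`, `bias`, `loa_low`, `loa_high`,
#'   `anova_table`, `mean_sem_a`, `mean_sem_b`.
#' @export
agreement_report <- function(paired, metric_name = "FEV1",
                             anova_mode = c("per_maneuver", "per_subject")) {
  anova_mode <- match.arg(anova_mode)
  ok <- stats::complete.cases(paired$value_device_a, paired$value_device_b)
  excl <- sum(!ok)
  paired <- paired[ok, , drop = FALSE]
  pr <- pearson(paired$value_device_a, paired$value_device_b)
  ba <- bland_altman(paired$value_device_a, paired$value_device_b)
  if (anova_mode == "per_subject") {
    agg_a <- stats::aggregate(value_device_a ~ subject_id + group, paired, mean)
    agg_b <- stats::aggregate(value_device_b ~ subject_id + group, paired, mean)
    vals <- c(agg_a$value_device_a, agg_b$value_device_b)
    dev <- rep(c("novel", "reference"), c(nrow(agg_a), nrow(agg_b)))
    grp <- c(agg_a$group, agg_b$group)
  } else {
    vals <- c(paired$value_device_a, paired$value_device_b)
    dev <- rep(c("novel", "reference"), each = nrow(paired))
    grp <- rep(paired$group, 2)
  }
  an <- two_factor_anova(vals, dev, grp)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(metric = metric_name, n_pairs = pr$n, n_excluded = excl,
                 pearson_r = pr$r, pearson_p = pr$p,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 anova_table = an,
                 mean_sem_a = c(mean = mean(paired$value_device_a),
                                sem = sem(paired$value_device_a)),
                 mean_sem_b = c(mean = mean(paired$value_device_b),
                                sem = sem(paired$value_device_b)),
                 bland_altman = ba),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result %s> n = %d pairs (%d excluded)\n",
              x$metric, x$n_pairs, x$n_excluded))
  cat(sprintf("  Pearson r = %.4f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  Bland-Altman bias %.4f, 95%% LoA [%.4f, %.4f]\n",
              x$bias, x$loa_low, x$loa_high))
  dev <- x$anova_table[x$anova_table$term == "device", ]
  cat(sprintf("  device effect: F = %.3f, p = %.3g\n", dev$f, dev$p))
  invisible(x)
}

#' Analyse a simulated cohort and tabulate paired maneuvers
#'
#' Runs the spirometry pipeline on every session of a [make_cohort()]
#' result and builds the long-format paired table (maneuver i on device A
#' pairs with maneuver i on device B).
#'
#' @param cohort A [make_cohort()] result.
#' @return `data.frame` with `subject_id`, `group`, `maneuver_index`,
#'   `metric`, `value_device_a`, `value_device_b`.
#' @export
analyze_cohort <- function(cohort) {
  rows <- list()
  for (s in cohort) {
    res <- lapply(s$sessions, function(ses) {
      cal <- ses$nominal_calibration
      if (is.null(cal)) cal <- default_calibration()
      analyze_session(ses$trace, cal)
    })
    nm <- min(length(res$device_a$maneuvers), length(res$device_b$maneuvers))
    for (i in seq_len(nm)) {
      ma <- res$device_a$maneuvers[[i]]
      mb <- res$device_b$maneuvers[[i]]
      for (metric in c("fev1", "fvc", "pef")) {
        rows[[length(rows) + 1L]] <-
          data.frame(subject_id = s$subject_id, group = s$group,
                     maneuver_index = i, metric = metric,
                     value_device_a = ma[[metric]],
                     value_device_b = mb[[metric]])
      }
    }
  }
  do.call(rbind, rows)
}

#' Full paired-device benchmark on a simulated cohort
#'
#' @param cohort A [make_cohort()] result.
#' @param metrics Metrics to report on.
#' @return Named list of [agreement_report()] results.
#' @export
benchmark_cohort <- function(cohort, metrics = c("fev1", "fvc")) {
  tab <- analyze_cohort(cohort)
  out <- lapply(metrics, function(m)
    agreement_report(tab[tab$metric == m, , drop = FALSE],
                     metric_name = toupper(m)))
  names(out) <- metrics
  out
}
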