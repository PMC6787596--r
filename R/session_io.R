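#' Write a raw trace to CSV
#'
#' Trace CSV dialect: UTF-8, '.' decimal, columns
#' `t_s, v_pressure_a, v_pressure_b, v_gas_no, v_gas_co`, preceded by
#' comment lines (`#`-prefixed) carrying the sample rate, a calibration
#' reference, and one line per annotation
#' (`# annotation: label,start_s,end_s`). Chosen for diff-ability and
#' spreadsheet compatibility.
#'
#' @param trace A [raw_trace()].
#' @param path Output file path.
#' @param calibration_ref Free-text calibration reference recorded in the
#'   header.
#' @param digits Decimal digits written for voltages (time gets
#'   `digits + 1`).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, calibration_ref = "default",
                            digits = 6) {
  stopifnot(inherits(trace, "raw_trace"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# openspiro trace v1",
               sprintf("# sample_rate_hz: %.10g", trace$sample_rate),
               sprintf("# calibration: %s", calibration_ref)), con)
  a <- trace$annotations
  for (i in seq_len(nrow(a)))
    writeLines(sprintf("# annotation: %s,%.6f,%.6f",
                       a$label[i], a$start_s[i], a$end_s[i]), con)
  fmt <- function(x, d) formatC(x, digits = d, format = "f")
  writeLines("t_s,v_pressure_a,v_pressure_b,v_gas_no,v_gas_co", con)
  writeLines(paste(fmt(trace$t, digits + 1), fmt(trace$v_pressure_a, digits),
                   fmt(trace$v_pressure_b, digits), fmt(trace$v_gas_no, digits),
                   fmt(trace$v_gas_co, digits), sep = ","), con)
  invisible(path)
}

#' Read a raw trace from CSV
#'
#' Parses the dialect written by [write_trace_csv()]. Columns may appear in
#' any order but all five must be present. Timestamps must be uniform to
#' within 1% of the sample period and runs of missing samples longer than
#' 0.5 s are rejected; both errors report the offending line number.
#'
#' @param path Input file path.
#' @return A [raw_trace()].
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  header <- lines[is_comment]
  n_head <- length(header) + 1L  # + column-name row

  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  sr <- get_field("sample_rate_hz")
  if (is.null(sr)) stopf("read_trace_csv: missing '# sample_rate_hz:' header")
  sr <- as.numeric(sr)

  ann_lines <- grep("^#\\s*annotation:", header, value = TRUE)
  ann <- data.frame(label = character(), start_s = numeric(),
                    end_s = numeric(), stringsAsFactors = FALSE)
  for (al in ann_lines) {
    parts <- strsplit(trimws(sub("^#\\s*annotation:", "", al)), ",")[[1]]
    ann <- rbind(ann, data.frame(label = trimws(parts[1]),
                                 start_s = as.numeric(parts[2]),
                                 end_s = as.numeric(parts[3])))
  }

  dat <- utils::read.csv(textConnection(lines[!is_comment]),
                         stringsAsFactors = FALSE)
  need <- c("t_s", "v_pressure_a", "v_pressure_b", "v_gas_no", "v_gas_co")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stopf("read_trace_csv: missing column(s): %s",
          paste(missing_cols, collapse = ", "))

  t <- dat$t_s
  period <- 1 / sr
  if (length(t) > 1) {
    dts <- diff(t)
    bad <- which(abs(dts - period) > 0.01 * period)
    if (length(bad))
      stopf("read_trace_csv: nonuniform timestamp at line %d (t = %.6f s, step %.6f s, expected %.6f s)",
            n_head + bad[1] + 1L, t[bad[1] + 1], dts[bad[1]], period)
  }
  max_run <- round(0.5 * sr)
  for (ch in need[-1]) {
    nas <- is.na(dat[[ch]]) | is.nan(dat[[ch]])
    if (any(nas)) {
      r <- rle(nas)
      if (any(r$values & r$lengths > max_run)) {
        i <- which(r$values & r$lengths > max_run)[1]
        at <- sum(r$lengths[seq_len(i - 1)]) + 1L
        stopf("read_trace_csv: NaN run > 0.5 s in %s starting at line %d",
              ch, n_head + at)
      }
    }
  }
  raw_trace(sr, t, dat$v_pressure_a, dat$v_pressure_b, dat$v_gas_no,
            dat$v_gas_co, ann)
}

#' Write / read a calibration profile
#'
#' Serialises a [sensor_calibration()] field-for-field to YAML (or JSON,
#' by file extension). A documented default profile ships with the package
#' (`system.file("extdata", "default_calibration.yaml", package =
#' "openspiro")`).
#'
#' @param cal A [sensor_calibration()].
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `path` invisibly (write); a [sensor_calibration()] (read).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "sensor_calibration"))
  x <- list(pressure_a = unclass(cal$pressure_a),
            pressure_b = unclass(cal$pressure_b),
            gas_no = unclass(cal$gas_no), gas_co = unclass(cal$gas_co),
            sample_rate = cal$sample_rate,
            fusion_low_edge = cal$fusion_low_edge,
            fusion_high_edge = cal$fusion_high_edge)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @rdname write_calibration
#' @param path File path.
#' @export
read_calibration <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  ps <- function(p) pressure_sensor_spec(p$name, p$flow_min, p$flow_max,
                                         p$orifice_coeff_k, p$v_offset,
                                         p$v_span, p$noise_sd, p$adc_bits,
                                         p$v_ref)
  gs <- function(g) gas_sensor_spec(g$analyte, g$sensitivity, g$v_baseline,
                                    g$detection_floor, g$range_max,
                                    g$noise_sd)
  sensor_calibration(ps(x$pressure_a), ps(x$pressure_b), gs(x$gas_no),
                     gs(x$gas_co), x$sample_rate, x$fusion_low_edge,
                     x$fusion_high_edge)
}

#' Write a session results report as JSON
#'
#' Serialises the analysis results of a session -- per-maneuver metrics
#' with units, the acceptability report, and gas readings -- together with
#' session metadata (id, timestamp, GPS tag, subject descriptors).
#'
#' @param path Output path.
#' @param session_id Identifier string.
#' @param spiro Result of [analyze_session()] (optional).
#' @param gas Result of [analyze_gas()] (optional).
#' @param gps Optional `c(lat, lon)`; latitude must be in \[-90, 90\] and
#'   longitude in \[-180, 180\].
#' @param subject Optional list of subject descriptors.
#' @return `path`, invisibly.
#' @export
write_session_json <- function(path, session_id, spiro = NULL, gas = NULL,
                               gps = NULL, subject = NULL) {
  if (!is.null(gps)) {
    if (abs(gps[[1]]) > 90 || abs(gps[[2]]) > 180)
      stopf("write_session_json: GPS coordinates out of range")
    gps <- list(lat_deg = gps[[1]], lon_deg = gps[[2]])
  }
  man <- NULL
  if (!is.null(spiro))
    man <- lapply(spiro$maneuvers, function(m)
      list(fev1_l = m$fev1, fvc_l = m$fvc, pef_l_per_s = m$pef,
           fev1_fvc_ratio = m$fev1_fvc_ratio, fet_s = m$fet,
           bev_l = m$bev, t0_s = m$t0, flags = m$flags))
  rep <- if (!is.null(spiro)) unclass(spiro$report) else NULL
  gas_out <- NULL
  if (!is.null(gas))
    gas_out <- list(
      no = unclass(gas$no)[setdiff(names(gas$no), "window")],
      co = unclass(gas$co)[setdiff(names(gas$co), "window")])
  out <- list(session_id = session_id,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              gps = gps, subject = subject, units = list(
                fev1_l = "L", fvc_l = "L", pef_l_per_s = "L/s", fet_s = "s",
                bev_l = "L", mean_conc = "ppm", mean_conc_ppb = "ppb"),
              maneuvers = man, grading = rep, gas = gas_out)
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
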