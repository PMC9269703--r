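# Data model and I/O for 3-sensor IMU recordings.

#' Construct a bending-and-return recording
#'
#' A recording holds the synchronous multi-channel time series of one
#' participant: three inertial sensors (SENS1 at T12, SENS2 at S2, SENS3 on
#' the lateral thigh), each with triaxial accelerometer (`Acc X/Y/Z`) and
#' gyroscope (`Gyr X/Y/Z`) channels sampled at a common frequency.
#'
#' The data are stored wide, one row per sample, with a `time` column in
#' seconds and one column per channel named `<SENSOR>_<Type>_<Axis>`
#' (e.g. `SENS1_Gyr_Y`). Derived channels (`AccA`, angular acceleration in
#' deg/s^2; `AngC`, drift-corrected angle in deg) use the same scheme.
#' SENS3 is mounted with a different orientation: its `-Gyr Z` channel
#' plays the role that `Gyr Y` plays for SENS1/SENS2.
#'
#' @param data A data frame with a numeric `time` column and one numeric
#'   column per channel. All 18 recorded channels must be present.
#' @param subject_id Participant identifier.
#' @param group Group label, `"CLBP"` or `"NLBP"`.
#' @param fs Sampling frequency in Hz (default 100).
#' @return A `br_recording`: a tibble with metadata attributes
#'   `subject_id`, `group` and `fs`.
#' @export
br_recording <- function(data, subject_id, group = c("NLBP", "CLBP"),
                         fs = 100) {
  group <- match.arg(group)
  data <- tibble::as_tibble(data)
  required <- c("time", channel_columns())
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("recording is missing channel column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "br_format_error")
  }
  not_num <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(paste0("non-numeric recording column(s): ",
                 paste(not_num, collapse = ", ")),
          class = "br_format_error")
  }
  structure(data,
            subject_id = as.character(subject_id),
            group = group, fs = fs,
            class = c("br_recording", class(data)))
}

#' @export
print.br_recording <- function(x, ...) {
  cat(sprintf("<br_recording> subject %s, group %s, %.0f Hz, %.1f s, %d channels\n",
              attr(x, "subject_id"), attr(x, "group"), attr(x, "fs"),
              nrow(x) / attr(x, "fs"), ncol(x) - 1L))
  NextMethod()
}

rec_fs <- function(rec) attr(rec, "fs")
rec_group <- function(rec) attr(rec, "group")
rec_subject <- function(rec) attr(rec, "subject_id")

# rebuild a recording around modified data, keeping metadata
rec_update <- function(rec, data) {
  structure(tibble::as_tibble(data),
            subject_id = rec_subject(rec), group = rec_group(rec),
            fs = rec_fs(rec), class = class(rec))
}

#' Read a recording from delimited text
#'
#' Reads one participant's recording from a delimited text file (comma or
#' tab separated, autodetected), one row per sample. A *layout* maps file
#' columns to channels; by default the file is expected to use the
#' package's own column names (`time`, `SENS1_Acc_X`, ...). Rows containing
#' non-numeric entries in mapped columns are rejected with a warning.
#'
#' @param path Path to a delimited text file.
#' @param layout Either `NULL` (columns already named canonically), a named
#'   character vector `c(canonical = "file column", ...)`, or the path to a
#'   YAML/JSON file holding such a map. A `time` entry is optional; when
#'   absent, time is reconstructed from `fs`.
#' @param subject_id,group,fs Recording metadata (see [br_recording()]).
#' @return A [br_recording()].
#' @export
read_recording <- function(path, layout = NULL, subject_id = "S1",
                           group = c("NLBP", "CLBP"), fs = 100) {
  group <- match.arg(group)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "br_format_error")
  }
  raw <- readr::read_delim(path, delim = detect_delim(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  map <- resolve_layout(layout)
  if (!is.null(map)) {
    missing_src <- setdiff(unname(map), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("layout names column(s) absent from file: ",
                   paste(missing_src, collapse = ", ")),
            class = "br_format_error")
    }
    raw <- raw[, unname(map)]
    names(raw) <- names(map)
  }
  missing_ch <- setdiff(channel_columns(), names(raw))
  if (length(missing_ch) > 0) {
    abort(paste0("file is missing channel column(s): ",
                 paste(missing_ch, collapse = ", ")),
          class = "br_format_error")
  }
  keep <- intersect(c("time", channel_columns(),
                      channel_columns(.derived_types)), names(raw))
  raw <- raw[, keep]
  num <- suppressWarnings(
    dplyr::mutate(raw, dplyr::across(dplyr::everything(), as.numeric)))
  bad <- !stats::complete.cases(num)
  if (any(bad)) {
    warn(sprintf("rejected %d row(s) with non-numeric entries", sum(bad)))
    num <- num[!bad, , drop = FALSE]
  }
  if (nrow(num) == 0) abort("no numeric rows in file", class = "br_format_error")
  if (!"time" %in% names(num)) {
    num$time <- (seq_len(nrow(num)) - 1) / fs
  }
  br_recording(num, subject_id = subject_id, group = group, fs = fs)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

resolve_layout <- function(layout) {
  if (is.null(layout)) return(NULL)
  if (is.character(layout) && is.null(names(layout)) && length(layout) == 1) {
    if (grepl("\\.ya?ml$", layout)) {
      layout <- unlist(yaml::read_yaml(layout))
    } else {
      layout <- unlist(jsonlite::read_json(layout, simplifyVector = TRUE))
    }
  }
  if (is.null(names(layout)) || any(names(layout) == "")) {
    abort("layout must be a named map canonical -> file column",
          class = "br_format_error")
  }
  layout
}

#' Write a recording to delimited text
#'
#' Emits the same one-row-per-sample text format [read_recording()] reads,
#' at full double precision so that a write/read round trip is bit-exact.
#'
#' @param rec A [br_recording()].
#' @param path Output file path; `.tsv` extension selects tab delimiters.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- tibble::as_tibble(rec)
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(),
                                        ~ sprintf("%.17g", .x)))
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Trim the warm-up period from a recording
#'
#' Restricts a recording to the analysis window `[t0, t1)`. With the
#' defaults (10 s to 70 s) a 100 Hz recording yields N = 6000 samples per
#' channel, the series length the entropy analysis assumes. Recordings
#' shorter than `t1` (e.g. tests stopped early) are rejected.
#'
#' @param rec A [br_recording()].
#' @param t0,t1 Window bounds in seconds (defaults 10 and 70).
#' @return The trimmed [br_recording()].
#' @export
trim_warmup <- function(rec, t0 = 10, t1 = 70) {
  fs <- rec_fs(rec)
  if (t1 <= t0) abort("empty analysis window: t1 must exceed t0",
                      class = "br_window_error")
  duration <- nrow(rec) / fs
  if (duration < t1 - 1e-9) {
    abort(sprintf("insufficient data: recording lasts %.2f s but t1 = %g s",
                  duration, t1),
          class = "br_insufficient_data")
  }
  idx <- seq.int(floor(t0 * fs) + 1L, floor(t1 * fs))
  rec_update(rec, rec[idx, , drop = FALSE])
}

#' Angular acceleration by numerical differentiation
#'
#' Differentiates an angular-velocity channel (deg/s) to angular
#' acceleration (deg/s^2) using central differences, with one-sided
#' differences at the endpoints so the output keeps the input length.
#'
#' @param x Numeric series, deg/s.
#' @param fs Sampling frequency, Hz.
#' @return Numeric series of `length(x)`, deg/s^2.
#' @export
angular_acceleration <- function(x, fs) {
  n <- length(x)
  if (n < 3) abort("need at least 3 samples to differentiate",
                   class = "br_insufficient_data")
  out <- numeric(n)
  out[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  out[1] <- (x[2] - x[1]) * fs
  out[n] <- (x[n] - x[n - 1]) * fs
  out
}

#' Drift-corrected angle by numerical integration
#'
#' Integrates an angular-velocity channel (deg/s) with the cumulative
#' trapezoidal rule and subtracts the least-squares straight line fitted
#' over the whole series, removing the linear drift that gyroscope bias
#' produces. The result has zero linear trend by construction.
#'
#' @inheritParams angular_acceleration
#' @return Numeric series of `length(x)`, deg.
#' @export
corrected_angle <- function(x, fs) {
  n <- length(x)
  if (n < 2) abort("need at least 2 samples to integrate",
                   class = "br_insufficient_data")
  t <- (seq_len(n) - 1) / fs
  ang <- pracma::cumtrapz(t, x)[, 1]
  stats::lsfit(t, ang)$residuals
}

#' Add derived kinematic channels to a recording
#'
#' Appends angular acceleration (`AccA X/Y/Z`, [angular_acceleration()])
#' and drift-corrected angle (`AngC X/Y/Z`, [corrected_angle()]) columns
#' for every gyroscope channel of every sensor.
#'
#' @param rec A [br_recording()].
#' @return The recording with 18 additional derived channel columns.
#' @export
add_derived_channels <- function(rec) {
  fs <- rec_fs(rec)
  df <- tibble::as_tibble(rec)
  for (sensor in .sensors) {
    for (axis in .axes) {
      gyr <- df[[paste(sensor, "Gyr", axis, sep = "_")]]
      df[[paste(sensor, "AccA", axis, sep = "_")]] <- angular_acceleration(gyr, fs)
      df[[paste(sensor, "AngC", axis, sep = "_")]] <- corrected_angle(gyr, fs)
    }
  }
  rec_update(rec, df)
}
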