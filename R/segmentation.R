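# Movement-cycle segmentation and length normalization.

#' Cycle segmentation parameters
#'
#' @param window Width of the rolling centered mean, in samples (odd;
#'   default 25, i.e. 0.25 s at 100 Hz).
#' @param threshold_frac Threshold as a fraction of the global amplitude
#'   above the global minimum of the smoothed series (0 < frac < 1;
#'   default 0.40).
#' @param n_points Normalized cycle length (default 450).
#' @return A `br_segmentation_params` list.
#' @export
segmentation_params <- function(window = 25, threshold_frac = 0.40,
                                n_points = 450) {
  if (window < 1 || window %% 2 == 0) {
    abort("window must be an odd positive number of samples",
          class = "br_param_error")
  }
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    abort("threshold_frac must lie strictly between 0 and 1",
          class = "br_param_error")
  }
  if (n_points < 2) abort("n_points must be >= 2", class = "br_param_error")
  structure(list(window = as.integer(window), threshold_frac = threshold_frac,
                 n_points = as.integer(n_points)),
            class = "br_segmentation_params")
}

#' Rolling centered mean
#'
#' Smooths a series with a centered moving average. At the edges the
#' window shrinks symmetrically (no padding, no invented samples): sample
#' i is averaged over `i - s ... i + s` with
#' `s = min((window - 1)/2, i - 1, n - i)`.
#'
#' @param x Numeric series.
#' @param width Odd window width in samples.
#' @return Smoothed series of `length(x)`.
#' @export
rolling_centered_mean <- function(x, width) {
  n <- length(x)
  if (width < 1 || width %% 2 == 0) {
    abort("width must be odd and >= 1", class = "br_param_error")
  }
  if (width > n) abort("width exceeds series length", class = "br_param_error")
  if (width == 1) return(x)
  h <- (width - 1L) %/% 2L
  i <- seq_len(n)
  s <- pmin(h, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  (cs[i + s + 1L] - cs[i - s]) / (2 * s + 1)
}

#' Segment bending-and-return cycles from Acc Z
#'
#' Detects cycles on the vertical accelerometer channel of the thoracic
#' sensor (Acc Z SENS1), whose pronounced minimum at deep flexion gives
#' the highest signal-to-noise ratio. Steps: (1) smooth with a rolling
#' centered mean; (2) set the threshold at `threshold_frac` of the global
#' amplitude above the global minimum of the smoothed series; (3) keep
#' only contiguous runs strictly below the threshold, so shallow local
#' minima above it are ignored; (4) take one minimum per run (its argmin,
#' earliest on ties). Consecutive deep-flexion minima delimit the cycles:
#' `k` minima give `k - 1` cycles. The mid-cycle limit markers — the
#' average position of two consecutive minima, i.e. the upright instants,
#' rounded to the nearest sample with ties toward the earlier sample —
#' are returned in the `midpoints` attribute.
#'
#' @param acc_z Numeric series (Acc Z of SENS1, already trimmed).
#' @param params A [segmentation_params()] object.
#' @return Integer vector of cycle-delimiting sample indices (the
#'   detected minima, strictly increasing), with attributes `midpoints`
#'   (rounded average positions of consecutive minima) and `threshold`.
#' @export
segment_cycles <- function(acc_z, params = segmentation_params()) {
  sm <- rolling_centered_mean(acc_z, params$window)
  lo <- min(sm); hi <- max(sm)
  thr <- lo + params$threshold_frac * (hi - lo)
  below <- sm < thr
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  if (length(keep) < 2) {
    abort("fewer than 2 below-threshold runs: no cycles detected",
          class = "br_no_cycles")
  }
  minima <- vapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    idx[which.min(sm[idx])]
  }, integer(1))
  # average position of consecutive minima, .5 rounding toward the
  # earlier sample
  mids <- (head(minima, -1) + tail(minima, -1)) / 2
  midpoints <- as.integer(ceiling(mids - 0.5))
  structure(as.integer(minima), midpoints = midpoints, threshold = thr)
}

#' Normalize segmented cycles to a fixed length
#'
#' Applies the cycle limits found on Acc Z of SENS1 to *every* channel of
#' the recording and resamples each cycle to exactly `n_points` samples by
#' linear interpolation over its own duration. Samples before the first
#' limit and after the last are partial cycles and are discarded.
#'
#' @param rec A trimmed [br_recording()].
#' @param boundaries Cycle limits from [segment_cycles()].
#' @param params A [segmentation_params()] object (uses `n_points`).
#' @param channels Channel columns to normalize (default: all recorded).
#' @return A `br_cycleset`: a tibble with columns `cycle`, `itime`
#'   (1 ... n_points) and one column per channel, plus attributes
#'   `boundaries`, `n_points`, `subject_id` and `group`.
#' @export
normalize_cycles <- function(rec, boundaries,
                             params = segmentation_params(),
                             channels = channel_columns()) {
  np <- params$n_points
  n_cyc <- length(boundaries) - 1L
  pieces <- vector("list", n_cyc)
  kept <- 0L
  for (k in seq_len(n_cyc)) {
    idx <- boundaries[k]:boundaries[k + 1]
    if (length(idx) < 2) {
      warn(sprintf("cycle %d shorter than 2 samples: skipped", k))
      next
    }
    kept <- kept + 1L
    xout <- seq(1, length(idx), length.out = np)
    cols <- lapply(rec[idx, channels, drop = FALSE], function(v) {
      approx(seq_along(idx), v, xout = xout)$y
    })
    pieces[[kept]] <- tibble::tibble(cycle = kept, itime = seq_len(np),
                                     !!!cols)
  }
  if (kept == 0) abort("no usable cycles", class = "br_no_cycles")
  out <- dplyr::bind_rows(pieces[seq_len(kept)])
  structure(out, boundaries = boundaries, n_points = np,
            subject_id = rec_subject(rec), group = rec_group(rec),
            class = c("br_cycleset", class(out)))
}

#' Pointwise mean and SD cycle
#'
#' Summarizes a cycle set for one channel as the mean and SD across cycles
#' at each normalized time point (itime). The SD is 0 when only one cycle
#' is present.
#'
#' @param cycles A `br_cycleset` from [normalize_cycles()] (or several
#'   row-bound together, e.g. per group).
#' @param channel Internal channel name, e.g. `"SENS2_Gyr_Y"`.
#' @return A tibble with columns `itime`, `mean` and `sd`.
#' @export
mean_cycle <- function(cycles, channel) {
  if (!is.data.frame(cycles) || nrow(cycles) == 0) {
    abort("empty cycle set", class = "br_no_cycles")
  }
  if (!channel %in% names(cycles)) {
    abort(paste0("unknown channel: ", channel), class = "br_config_error")
  }
  cycles |>
    dplyr::group_by(.data$itime) |>
    dplyr::summarise(
      mean = mean(.data[[channel]]),
      sd = if (dplyr::n() > 1) stats::sd(.data[[channel]]) else 0,
      .groups = "drop")
}

#' Segment and normalize a whole recording
#'
#' Convenience wrapper: runs [segment_cycles()] on `SENS1_Acc_Z` and
#' [normalize_cycles()] on all recorded channels.
#'
#' @inheritParams normalize_cycles
#' @param params A [segmentation_params()] object.
#' @return A `br_cycleset`.
#' @export
segment_recording <- function(rec, params = segmentation_params(),
                              channels = channel_columns()) {
  b <- segment_cycles(rec$SENS1_Acc_Z, params)
  normalize_cycles(rec, b, params, channels)
}
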