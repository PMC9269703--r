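# Synthetic bending-and-return cohort generator with ground truth.

#' Synthetic subject parameters
#'
#' Parameters of the quasi-periodic bending-and-return signal model. Each
#' cycle is a smooth flexion-return excursion of the trunk angle (a
#' difference of raised cosines peaking at deep flexion mid-cycle), with
#' per-cycle period and amplitude jitter. The thoracic, pelvic and thigh
#' sensors see scaled, slightly lagged copies of the movement; gyroscope
#' channels carry its angular velocity, accelerometer channels a gravity
#' projection of the angle (so Acc Z of SENS1 dips once per cycle at deep
#' flexion) plus structured noise. Movement complexity is controlled by
#' the *colour* of the noise and of the cycle-to-cycle perturbations: a
#' mixing weight blends white (high-entropy) with autocorrelated
#' (low-entropy) components.
#'
#' Group presets encode the study's contrast directions: chronic low back
#' pain patients move with lower peak angular velocity and lower
#' complexity (more stereotyped cycles) than healthy subjects.
#'
#' @param group `"NLBP"` or `"CLBP"` (chooses the preset that the
#'   remaining arguments override).
#' @param duration Recording length, s (default 70).
#' @param fs Sampling frequency, Hz (default 100).
#' @param period_mean,period_sd Cycle period mean and SD, s (defaults
#'   1.43 and 0.15, consistent with ~42 cycles per 60 s).
#' @param peak_velocity_mean,peak_velocity_sd Between-subject mean and SD
#'   of the peak flexion angular velocity, deg/s (presets: NLBP 190/25,
#'   CLBP 140/25).
#' @param amplitude_cv Within-subject cycle-to-cycle coefficient of
#'   variation of the flexion excursion (default 0.04: the excursion is
#'   anchored by the physical target being touched, so it varies much
#'   less than the movement's timing; per-cycle velocity additionally
#'   inherits the ~10% period jitter).
#' @param white_frac Mixing weight (variance fraction) of white vs
#'   autocorrelated perturbations, in both the additive noise and the
#'   cycle-to-cycle jitter; higher = more complex (presets: NLBP 0.8,
#'   CLBP 0.25).
#' @param white_frac_sd Between-subject SD of the mixing weight (default
#'   0.1, truncated to (0.02, 0.98)): entropy varies between subjects of
#'   one group, as observed cohorts do.
#' @param noise_sd_gyr Additive structured-noise SD on gyroscope
#'   channels, deg/s, at the healthy reference amplitude (190 deg/s peak
#'   velocity); scaled with the subject's drawn amplitude so that the
#'   noise-to-signal ratio is amplitude-independent (default 6).
#' @param noise_sd_acc Additive structured-noise SD on accelerometer
#'   channels, g, at the reference amplitude (default 0.025).
#' @param ar_phi AR(1) coefficient of the correlated noise component
#'   (default 0.95).
#' @param lobe_skew Second-harmonic weight of the velocity pulse
#'   (0 <= skew < 0.5, default 0.3): skews the flexion lobe so peak
#'   velocity is reached early in flexion and late in return, while
#'   keeping the waveform smooth; deep flexion stays at mid-cycle.
#' @param pelvis_ratio,hip_ratio Amplitude of the pelvis and thigh
#'   movement relative to the trunk (defaults 0.55, 0.30).
#' @param pelvis_lag,hip_lag Lag of pelvis and thigh movement, s
#'   (defaults 0.06, 0.10).
#' @param warmup_ramp Seconds over which amplitude builds up at the start
#'   (default 5; removed by [trim_warmup()]).
#' @return A `br_synth_params` list.
#' @export
synth_params <- function(group = c("NLBP", "CLBP"), duration = 70,
                         fs = 100, period_mean = 1.43, period_sd = 0.15,
                         peak_velocity_mean = NULL,
                         peak_velocity_sd = 25, amplitude_cv = 0.04,
                         white_frac = NULL, white_frac_sd = 0.1,
                         noise_sd_gyr = 6,
                         noise_sd_acc = 0.025, ar_phi = 0.95,
                         lobe_skew = 0.3, pelvis_ratio = 0.55,
                         hip_ratio = 0.30, pelvis_lag = 0.06,
                         hip_lag = 0.10, warmup_ramp = 5) {
  group <- match.arg(group)
  if (is.null(peak_velocity_mean)) {
    peak_velocity_mean <- if (group == "NLBP") 190 else 140
  }
  if (is.null(white_frac)) {
    white_frac <- if (group == "NLBP") 0.8 else 0.25
  }
  stopifnot(duration > 0, fs > 0, period_mean > 0, period_sd >= 0,
            peak_velocity_mean > 0, peak_velocity_sd >= 0,
            amplitude_cv >= 0, white_frac >= 0, white_frac <= 1,
            white_frac_sd >= 0,
            noise_sd_gyr >= 0, noise_sd_acc >= 0,
            lobe_skew >= 0, lobe_skew < 0.5)
  structure(as.list(environment()), class = "br_synth_params")
}

# white/AR(1) variance mixture, unit marginal SD
structured_noise <- function(n, white_frac, phi) {
  if (n == 0) return(numeric(0))
  ar <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - phi^2)), phi,
                                 method = "recursive"))
  sqrt(white_frac) * rnorm(n) + sqrt(1 - white_frac) * ar
}

# smooth excursion profile on u in [0, 1): a difference of raised
# cosines, 0 at both ends, 1 at u = 0.5 (deep flexion); beta skews the
# velocity lobes in time without introducing curvature kinks
excursion_profile <- function(u, beta) {
  ((1 - cos(2 * pi * u)) + (beta / 2) * (1 - cos(4 * pi * u))) / 2
}

# peak of the normalized angular-velocity profile pi*(sin 2pi u +
# beta sin 4pi u), used to convert peak velocity <-> excursion angle
profile_peak_velocity <- function(beta) {
  u <- seq(0, 0.5, by = 1e-4)
  pi * max(sin(2 * pi * u) + beta * sin(4 * pi * u))
}

#' Generate one synthetic subject
#'
#' Simulates a 3-sensor recording of the bending-and-return test under
#' the signal model of [synth_params()], together with its ground truth.
#' Deterministic given `seed`.
#'
#' @param params A [synth_params()] object.
#' @param subject_id Identifier stored in the recording.
#' @param seed Integer seed for all randomness in this subject.
#' @return A list with elements `recording` (a [br_recording()], 0 to
#'   `duration` s, untrimmed) and `truth` (list: per-cycle onset times
#'   `cycle_onsets` s, deep-flexion times `flexion_times` s, per-cycle
#'   peak velocities `peak_velocities` deg/s, the drawn subject peak
#'   velocity, the parameters and the seed).
#' @export
generate_subject <- function(params, subject_id = "S1", seed = 1) {
  stopifnot(inherits(params, "br_synth_params"))
  p <- params
  withr::with_seed(as.integer(seed), {
    n <- round(p$duration * p$fs)
    t <- (seq_len(n) - 1) / p$fs
    # subject's own complexity weight
    wf <- min(max(p$white_frac + p$white_frac_sd * rnorm(1), 0.02), 0.98)
    # cycle onsets: accumulate jittered periods past the end
    n_max <- ceiling(p$duration / max(p$period_mean - 4 * p$period_sd,
                                      0.3 * p$period_mean)) + 2
    periods <- pmax(p$period_mean +
                      p$period_sd * structured_noise(n_max, wf,
                                                     0.5),
                    0.3 * p$period_mean)
    onsets <- cumsum(c(0, periods))
    onsets <- onsets[onsets < p$duration]
    n_cyc <- length(onsets) - 1   # complete cycles fully inside the record
    # subject-level peak velocity and per-cycle amplitude jitter
    v_subj <- max(p$peak_velocity_mean + p$peak_velocity_sd * rnorm(1),
                  0.3 * p$peak_velocity_mean)
    amp <- pmax(1 + p$amplitude_cv *
                  structured_noise(length(onsets), wf, 0.8),
                0.2)
    # peak flexion angle, deg: the target excursion is a property of the
    # task (touching the stool), so it is set by the subject's typical
    # velocity and the *mean* period, with small per-cycle jitter;
    # peak velocity of theta * p(u / T) is theta * vpk(beta) / T
    cyc_of_t <- findInterval(t, onsets)
    T_c <- periods[seq_along(onsets)]   # period of the cycle at each onset
    vpk <- profile_peak_velocity(p$lobe_skew)
    theta_subj <- v_subj * p$period_mean / vpk
    u <- (t - onsets[cyc_of_t]) / T_c[cyc_of_t]
    ramp <- pmin(t / p$warmup_ramp, 1)
    theta <- theta_subj * amp[cyc_of_t] *
      excursion_profile(u, p$lobe_skew) * ramp
    lagged <- function(x, lag) {
      s <- round(lag * p$fs)
      c(rep(x[1], s), x[seq_len(n - s)])
    }
    theta_p <- p$pelvis_ratio * lagged(theta, p$pelvis_lag)
    theta_h <- p$hip_ratio * lagged(theta, p$hip_lag)
    # noise scales with the subject's movement amplitude (relative to the
    # healthy-preset reference) so that noise colour, not noise-to-signal
    # ratio, carries the complexity contrast; the flexion-axis gyroscope
    # channels share a common-mode component (trunk micro-adjustments
    # seen by all sensors) that partially cancels in difference series
    k <- v_subj / 190
    g_sd <- p$noise_sd_gyr * k
    a_sd <- p$noise_sd_acc * k
    shared <- structured_noise(n, wf, p$ar_phi)
    g_noise <- function() g_sd * structured_noise(n, wf, p$ar_phi)
    gy_noise <- function() {
      g_sd * (sqrt(0.7) * shared +
                sqrt(0.3) * structured_noise(n, wf, p$ar_phi))
    }
    a_noise <- function() a_sd * structured_noise(n, wf, p$ar_phi)
    v_t <- c(0, diff(theta)) * p$fs
    v_p <- c(0, diff(theta_p)) * p$fs
    v_h <- c(0, diff(theta_h)) * p$fs
    rad <- pi / 180
    df <- tibble::tibble(
      time = t,
      # thoracic sensor: gravity projections of the trunk angle
      SENS1_Acc_X = sin(theta * rad) + 0.5 * a_noise(),
      SENS1_Acc_Y = 0.06 * sin(2 * pi * t / 3) + a_noise(),
      SENS1_Acc_Z = cos(theta * rad) + a_noise(),
      SENS1_Gyr_X = 8 * sin(theta * rad) + g_noise(),
      SENS1_Gyr_Y = v_t + gy_noise(),
      SENS1_Gyr_Z = 0.05 * v_t + g_noise(),
      # pelvic sensor
      SENS2_Acc_X = sin(theta_p * rad) + 0.5 * a_noise(),
      SENS2_Acc_Y = 0.04 * sin(2 * pi * t / 3 + 1) + a_noise(),
      SENS2_Acc_Z = cos(theta_p * rad) + a_noise(),
      SENS2_Gyr_X = 5 * sin(theta_p * rad) + g_noise(),
      SENS2_Gyr_Y = v_p + gy_noise(),
      SENS2_Gyr_Z = 0.08 * v_p + g_noise(),
      # thigh sensor: different axis convention, -Gyr Z tracks the hip
      SENS3_Acc_X = sin(theta_h * rad) + 0.5 * a_noise(),
      SENS3_Acc_Y = 0.03 * sin(2 * pi * t / 3 + 2) + a_noise(),
      SENS3_Acc_Z = cos(theta_h * rad) + a_noise(),
      SENS3_Gyr_X = 4 * sin(theta_h * rad) + g_noise(),
      SENS3_Gyr_Y = 0.05 * v_h + g_noise(),
      SENS3_Gyr_Z = -(v_h + gy_noise()))
    # ground truth: deep flexion (Acc Z minimum) at mid-cycle
    flexion_times <- onsets[seq_len(n_cyc)] + 0.5 * T_c[seq_len(n_cyc)]
    truth <- list(
      cycle_onsets = onsets[seq_len(n_cyc)],
      flexion_times = flexion_times,
      peak_velocities = v_subj * amp[seq_len(n_cyc)],
      subject_peak_velocity = v_subj,
      n_cycles = n_cyc,
      params = p, seed = as.integer(seed))
    list(recording = br_recording(df, subject_id = subject_id,
                                  group = p$group, fs = p$fs),
         truth = truth)
  })
}

#' Generate a labelled synthetic cohort
#'
#' Generates `n` healthy (NLBP) and `n` patient (CLBP) subjects with
#' per-subject seeds derived from `seed`. Passing the same params for
#' both groups gives a null cohort with no group contrast.
#'
#' @param params_nlbp,params_clbp [synth_params()] presets for the two
#'   groups.
#' @param n Subjects per group (default 20).
#' @param seed Base seed; subject `i` of group g uses
#'   `seed * 1000 + i` (+500 for CLBP).
#' @return A `br_cohort` tibble: `subject_id`, `group`, `seed`,
#'   list-columns `recording` and `truth`.
#' @export
generate_cohort <- function(params_nlbp = synth_params("NLBP"),
                            params_clbp = synth_params("CLBP"),
                            n = 20, seed = 1) {
  stopifnot(n >= 1)
  base <- as.integer(seed) * 1000L
  rows <- purrr::map_dfr(seq_len(2 * n), function(i) {
    clbp <- i > n
    prm <- if (clbp) params_clbp else params_nlbp
    sid <- sprintf("%s%02d", if (clbp) "P" else "H", ((i - 1) %% n) + 1)
    sseed <- base + if (clbp) 500L + i - n else i
    sub <- generate_subject(prm, subject_id = sid, seed = sseed)
    tibble::tibble(subject_id = sid,
                   group = if (clbp) "CLBP" else "NLBP",
                   seed = sseed,
                   recording = list(sub$recording),
                   truth = list(sub$truth))
  })
  structure(rows, class = c("br_cohort", class(rows)))
}

#' Trim every recording of a cohort
#'
#' @param cohort A `br_cohort`.
#' @param t0,t1 Analysis window, s (defaults 10 and 70).
#' @return The cohort with trimmed recordings.
#' @export
trim_cohort <- function(cohort, t0 = 10, t1 = 70) {
  cohort$recording <- purrr::map(cohort$recording, trim_warmup,
                                 t0 = t0, t1 = t1)
  cohort
}

#' Write / read a cohort as delimited text plus manifest
#'
#' One recording file per subject plus `manifest.json` (labels, seeds,
#' ground-truth cycle times and generator parameters) so a written cohort
#' can be re-read or consumed by the file-based pipeline.
#'
#' @param cohort A `br_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly, or the re-read `br_cohort` (without truth
#'   when the manifest lacks it).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.csv", cohort$subject_id)
  purrr::walk2(cohort$recording, files,
               ~ write_recording(.x, file.path(dir, .y)))
  manifest <- list(
    subjects = purrr::pmap(
      list(cohort$subject_id, cohort$group, cohort$seed, files,
           cohort$truth),
      function(sid, grp, sd, f, tr) {
        list(subject_id = sid, group = grp, seed = sd, file = f,
             fs = tr$params$fs,
             cycle_onsets = tr$cycle_onsets,
             flexion_times = tr$flexion_times,
             n_cycles = tr$n_cycles)
      }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  rows <- purrr::map_dfr(manifest$subjects, function(s) {
    rec <- read_recording(file.path(dir, s$file), subject_id = s$subject_id,
                          group = s$group, fs = s$fs %||% 100)
    tibble::tibble(subject_id = s$subject_id, group = s$group,
                   seed = s$seed %||% NA_integer_,
                   recording = list(rec),
                   truth = list(list(
                     cycle_onsets = unlist(s$cycle_onsets),
                     flexion_times = unlist(s$flexion_times),
                     n_cycles = s$n_cycles %||% NA_integer_)))
  })
  structure(rows, class = c("br_cohort", class(rows)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
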