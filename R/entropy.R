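# Sample Entropy and complexity factors.

#' Sample Entropy parameters
#'
#' Configuration for [sample_entropy()]: template length `m`, tolerance
#' expressed as a fraction of the series SD, and the conventions used for
#' template counting and for the match comparison. Defaults follow the
#' standard parameterization for kinematic time series: m = 2, r = 0.2 SD,
#' applied here to N = 6000-point series (60 s at 100 Hz).
#'
#' @param m Template (vector) length, >= 1. Default 2.
#' @param r_coeff Tolerance as a fraction of the sample SD of the series
#'   (> 0). Default 0.2.
#' @param n Optional expected series length; when given,
#'   [sample_entropy()] checks the input length against it.
#' @param templates `"n-m"` (default) counts N - m template vectors for
#'   both lengths m and m + 1 (Richman-Moorman); `"n-m-1"` uses N - m - 1.
#' @param match `"leq"` (default) counts a pair as matching when its
#'   Chebyshev distance is `<= r`; `"lt"` requires `< r`.
#' @return A `br_sampen_params` list.
#' @export
sampen_params <- function(m = 2, r_coeff = 0.2, n = NULL,
                          templates = c("n-m", "n-m-1"),
                          match = c("leq", "lt")) {
  templates <- match.arg(templates)
  match <- match.arg(match)
  stopifnot(m >= 1, r_coeff > 0)
  structure(list(m = as.integer(m), r_coeff = r_coeff, n = n,
                 templates = templates, match = match),
            class = "br_sampen_params")
}

sampen_result <- function(A, B, m, r) {
  defined <- is.finite(A) && is.finite(B) && A > 0 && B > 0
  value <- if (defined) -log(A / B) else NA_real_
  # A == B == 0 distance-wise only when no templates at all; constant
  # series give A == B > 0 and value 0.
  structure(list(value = value, A = A, B = B, defined = defined,
                 m = m, r = r),
            class = "br_sampen")
}

#' @export
print.br_sampen <- function(x, ...) {
  cat(sprintf("SampEn = %s (m = %d, r = %.4g; A = %.0f, B = %.0f%s)\n",
              if (x$defined) sprintf("%.4f", x$value) else "undefined",
              x$m, x$r, x$A, x$B,
              if (x$defined) "" else "; no template matches"))
  invisible(x)
}

#' @export
tidy.br_sampen <- function(x, ...) {
  tibble::tibble(value = x$value, A = x$A, B = x$B, defined = x$defined,
                 m = x$m, r = x$r)
}

#' Sample Entropy of a time series
#'
#' Computes SampEn = -ln(A/B), where B counts pairs of length-`m` template
#' vectors whose Chebyshev distance is within the tolerance r =
#' `r_coeff` * SD(x), and A counts the same for length-(m+1) vectors.
#' Self-matches are excluded. Both template sets contain N - m vectors
#' (Richman-Moorman counting). Lower values indicate a more regular,
#' stereotyped signal; higher values a more complex one.
#'
#' A constant series has SD 0, hence r = 0; with the default `<=`
#' comparison all templates still match (distance 0) and SampEn is exactly
#' 0. When no length-(m+1) pair matches (A = 0), the result is flagged
#' undefined rather than infinite, and propagates as a missing value.
#'
#' @param x Numeric series.
#' @param params A [sampen_params()] object.
#' @return A `br_sampen` result with fields `value`, `A`, `B`, `defined`,
#'   `m` and `r`.
#' @export
sample_entropy <- function(x, params = sampen_params()) {
  stopifnot(inherits(params, "br_sampen_params"))
  n <- length(x)
  if (!is.null(params$n) && n != params$n) {
    abort(sprintf("series has %d points but params$n = %d", n, params$n))
  }
  if (n <= params$m) abort("series too short for template length m",
                           class = "br_insufficient_data")
  r <- params$r_coeff * sd(x)
  counts <- sampen_counts_cpp(as.numeric(x), params$m, r,
                              params$match == "leq",
                              params$templates == "n-m-1")
  if (anyNA(counts)) counts <- c(0, 0)   # a single template has no pairs
  sampen_result(counts[1], counts[2], params$m, r)
}

#' Brute-force Sample Entropy (reference oracle)
#'
#' A deliberately plain re-statement of the SampEn definition with explicit
#' double loops over template pairs, used as the ground truth that the
#' optimized [sample_entropy()] is tested against. Quadratic in the series
#' length; intended for short series only.
#'
#' @inheritParams sample_entropy
#' @param r_absolute Optional absolute tolerance overriding
#'   `params$r_coeff * SD(x)` (useful for hand-enumerable cases).
#' @return A `br_sampen` result.
#' @export
sample_entropy_bruteforce <- function(x, params = sampen_params(),
                                      r_absolute = NULL) {
  stopifnot(inherits(params, "br_sampen_params"))
  n <- length(x)
  if (n <= params$m) abort("series too short for template length m",
                           class = "br_insufficient_data")
  m <- params$m
  r <- if (is.null(r_absolute)) params$r_coeff * sd(x) else r_absolute
  n_templ <- if (params$templates == "n-m-1") n - m - 1 else n - m
  leq <- params$match == "leq"
  within_tol <- function(d) if (leq) d <= r else d < r
  A <- 0; B <- 0
  for (i in seq_len(n_templ - 1)) {
    for (j in seq.int(i + 1, n_templ)) {
      d_m <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (within_tol(d_m)) {
        B <- B + 1
        d_m1 <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (within_tol(d_m1)) A <- A + 1
      }
    }
  }
  sampen_result(A, B, m, r)
}

#' Lumbar and hip flexion complexity factors
#'
#' The complexity factors summarize how complex the *relative* sagittal
#' angular velocities of the lumbo-pelvic-hip complex are. The pelvis
#' channel (Gyr Y of SENS2) is subtracted from the thoracic channel
#' (Gyr Y of SENS1) and from the thigh channel (-Gyr Z of SENS3; SENS3 is
#' mounted with a different orientation), and SampEn of each difference
#' series is computed with the tolerance taken from that series' own SD:
#'
#' * LCF (lumbar flexion complexity factor) = SampEn(Gyr Y SENS1 - Gyr Y SENS2)
#' * HCF (hip flexion complexity factor) = SampEn(-Gyr Z SENS3 - Gyr Y SENS2)
#'
#' @param rec A trimmed [br_recording()].
#' @param params A [sampen_params()] object applied to both factors.
#' @return A tibble with columns `factor` ("LCF", "HCF"), `value`, `A`,
#'   `B` and `defined`.
#' @export
complexity_factors <- function(rec, params = sampen_params()) {
  needed <- c("SENS1_Gyr_Y", "SENS2_Gyr_Y", "SENS3_Gyr_Z")
  missing_ch <- setdiff(needed, names(rec))
  if (length(missing_ch) > 0) {
    abort(paste0("missing sensor channel(s): ",
                 paste(missing_ch, collapse = ", ")),
          class = "br_config_error")
  }
  lcf_in <- rec$SENS1_Gyr_Y - rec$SENS2_Gyr_Y
  hcf_in <- (-rec$SENS3_Gyr_Z) - rec$SENS2_Gyr_Y
  res <- lapply(list(LCF = lcf_in, HCF = hcf_in), function(x) {
    if (sd(x) == 0) {
      # identically equal sensors: zero difference series, zero complexity
      sampen_result(1, 1, params$m, 0)
    } else {
      sample_entropy(x, params)
    }
  })
  tibble::tibble(
    factor = names(res),
    value = unname(vapply(res, `[[`, numeric(1), "value")),
    A = unname(vapply(res, `[[`, numeric(1), "A")),
    B = unname(vapply(res, `[[`, numeric(1), "B")),
    defined = unname(vapply(res, `[[`, logical(1), "defined")))
}

#' SampEn of every recorded channel of a recording
#'
#' Convenience wrapper computing [sample_entropy()] for all 18 recorded
#' channels (optionally restricted), returning a tidy table.
#'
#' @param rec A trimmed [br_recording()].
#' @param params A [sampen_params()] object.
#' @param channels Internal channel names (default: all 18 recorded).
#' @return A tibble with columns `channel` (display name, e.g.
#'   "Gyr Y SENS1"), `value` and `defined`.
#' @export
channel_entropy <- function(rec, params = sampen_params(),
                            channels = channel_columns()) {
  res <- lapply(channels, function(ch) sample_entropy(rec[[ch]], params))
  tibble::tibble(
    channel = channel_display(channels),
    value = vapply(res, `[[`, numeric(1), "value"),
    defined = vapply(res, `[[`, logical(1), "defined"))
}
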