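# Cycle segmentation, normalization and mean cycles.

test_that("rolling centered mean smooths correctly and shrinks at edges", {
  expect_equal(rolling_centered_mean(rep(3, 50), 25), rep(3, 50))
  expect_equal(rolling_centered_mean(1:10, 1), 1:10)
  # impulse: plateau of 1/25 over 25 interior samples
  x <- rep(0, 100); x[50] <- 1
  sm <- rolling_centered_mean(x, 25)
  expect_equal(sum(sm[38:62] == 1 / 25), 25)
  expect_equal(sm[c(37, 63)], c(0, 0))
  # symmetric shrink: first sample is its own window
  y <- c(10, rep(0, 30))
  expect_equal(rolling_centered_mean(y, 25)[1], 10)
  expect_error(rolling_centered_mean(1:10, 4), class = "br_param_error")
  expect_error(rolling_centered_mean(1:10, 11), class = "br_param_error")
})

test_that("a cosine with 10 minima segments into 9 cycles with midpoint limits", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)      # 10 periods of a 1 Hz cosine
  x <- cos(2 * pi * t)
  b <- segment_cycles(x, segmentation_params())
  # minima at t = 0.5, 1.5, ..., 9.5 -> samples 51, 151, ..., 951
  expect_length(b, 10)
  expect_true(all(abs(b - seq(51, 951, by = 100)) <= 1))
  expect_equal(length(b) - 1, 9)              # 9 cycles
  mids <- attr(b, "midpoints")
  expect_length(mids, 9)
  expect_true(all(abs(mids - seq(101, 901, by = 100)) <= 1))
})

test_that("shallow local minima above the threshold are ignored by run gating", {
  fs <- 100
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  # deep troughs once per second plus a shallow ripple that stays above
  # the 40% threshold
  x <- cos(2 * pi * t) + 0.15 * cos(2 * pi * 7 * t)
  b <- segment_cycles(x, segmentation_params())
  expect_length(b, 6)
  expect_true(all(diff(b) > 50))
})

test_that("segmentation is invariant to offset and positive rescaling", {
  sub <- generate_subject(synth_params("NLBP"), seed = 21)
  x <- trim_warmup(sub$recording)$SENS1_Acc_Z
  b0 <- segment_cycles(x)
  expect_identical(as.integer(segment_cycles(x + 100)), as.integer(b0))
  expect_identical(as.integer(segment_cycles(x * 50)), as.integer(b0))
})

test_that("too few minima raise a no-cycles error", {
  expect_error(segment_cycles(c(rep(1, 30), rep(0, 5), rep(1, 30)),
                              segmentation_params(window = 3)),
               class = "br_no_cycles")
})

test_that("segmentation recovers generator truth on a synthetic subject", {
  sub <- generate_subject(synth_params("NLBP"), seed = 42)
  rec <- trim_warmup(sub$recording)
  b <- segment_cycles(rec$SENS1_Acc_Z)
  truth_t <- sub$truth$flexion_times
  truth_t <- truth_t[truth_t >= 10 & truth_t < 70]
  n_true <- length(truth_t) - 1
  expect_gte(length(b) - 1, n_true - 1)
  expect_lte(length(b) - 1, n_true + 2)
  det_t <- 10 + (b - 1) / 100
  err <- vapply(truth_t, function(tt) min(abs(det_t - tt)) * 100,
                numeric(1))
  expect_gte(mean(err <= 5), 0.95)
})

test_that("cycles resample to exactly n_points with identity and linearity preserved", {
  fs <- 100
  # one cycle spanning exactly 450 samples: identity resampling
  n <- 1000
  ramp <- seq_len(n)
  rec <- toy_recording(n, overrides = list(SENS2_Gyr_Y = ramp))
  b <- structure(c(100L, 549L, 900L), midpoints = c(300L, 700L))
  cyc <- normalize_cycles(rec, b)
  expect_equal(unique(table(cyc$cycle)), 450L)
  c1 <- cyc$SENS2_Gyr_Y[cyc$cycle == 1]
  expect_equal(c1, ramp[100:549])            # 450 samples preserved as-is
  # any-length linear ramp stays a ramp with identical endpoints
  c2 <- cyc$SENS2_Gyr_Y[cyc$cycle == 2]
  expect_equal(c2[1], 549)
  expect_equal(c2[450], 900)
  expect_equal(c2, seq(549, 900, length.out = 450))
})

test_that("resampling preserves the energy of a sine cycle to 1%", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 3 * t)
  rec <- toy_recording(length(t), overrides = list(SENS1_Gyr_Y = x))
  b <- structure(c(1L, 201L), midpoints = 101L)
  cyc <- normalize_cycles(rec, b)
  e_orig <- mean(x[1:201]^2)
  e_new <- mean(cyc$SENS1_Gyr_Y^2)
  expect_lt(abs(e_new - e_orig) / e_orig, 0.01)
})

test_that("degenerate cycles are skipped with a warning", {
  rec <- toy_recording(100)
  b <- structure(c(10L, 10L, 60L), midpoints = c(10L, 35L))
  expect_warning(cyc <- normalize_cycles(rec, b), "skipped")
  expect_equal(max(cyc$cycle), 1)
})

test_that("mean cycle is the pointwise mean with SD zero for duplicated cycles", {
  rec <- toy_recording(900, overrides = list(
    SENS2_Gyr_Y = rep(sin(seq_len(300) / 20), 3)))
  b <- structure(c(1L, 301L, 601L), midpoints = c(150L, 450L))
  cyc <- normalize_cycles(rec, b)
  mc <- mean_cycle(cyc, "SENS2_Gyr_Y")
  expect_equal(nrow(mc), 450)
  expect_equal(max(abs(mc$sd)), 0)
  # two distinct cycles: mean = (a + b) / 2 pointwise
  a <- cyc$SENS2_Gyr_Y[cyc$cycle == 1]
  rec2 <- toy_recording(900, overrides = list(
    SENS2_Gyr_Y = c(rep(1, 300), rep(3, 600))))
  cyc2 <- normalize_cycles(rec2, b)
  mc2 <- mean_cycle(cyc2, "SENS2_Gyr_Y")
  expect_true(all(abs(mc2$mean[mc2$itime <= 448] - 2) < 1e-9))
  expect_error(mean_cycle(cyc[0, ], "SENS2_Gyr_Y"), class = "br_no_cycles")
})

test_that("patients show a shallower mean-cycle velocity trough than healthy subjects", {
  cohort <- small_cohort(n = 6, seed = 11)
  sets <- purrr::map2_dfr(cohort$recording, cohort$group, function(rec, g) {
    dplyr::mutate(tibble::as_tibble(segment_recording(rec)), group = g)
  })
  mins <- sets |>
    dplyr::group_by(group) |>
    dplyr::group_map(~ min(mean_cycle(.x, "SENS2_Gyr_Y")$mean))
  names(mins) <- sort(unique(sets$group))
  expect_lt(abs(mins$CLBP), abs(mins$NLBP))
})

test_that("boundaries never overlap and cycle samples fit inside the series", {
  cohort <- small_cohort(n = 6, seed = 11)
  for (rec in cohort$recording[1:4]) {
    b <- segment_cycles(rec$SENS1_Acc_Z)
    expect_true(all(diff(b) > 0))
    lens <- diff(b) + 1
    expect_lte(sum(lens - 1) + 1, nrow(rec))
    expect_true(all(b >= 1 & b <= nrow(rec)))
  }
})
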