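# Sample Entropy: oracle, invariances, complexity factors.

test_that("a constant series has SampEn exactly 0", {
  res <- sample_entropy(rep(4.2, 500))
  expect_true(res$defined)
  expect_identical(res$value, 0)
  expect_equal(res$A, res$B)
  res_bf <- sample_entropy_bruteforce(rep(4.2, 100))
  expect_identical(res_bf$value, 0)
})

test_that("brute-force counts match a hand enumeration on 1..7 with absolute tolerance", {
  # m = 2, r = 0.5 absolute: templates (1,2)..(5,6); all pairwise
  # Chebyshev distances are multiples of 1 > 0.5, except nothing matches
  res <- sample_entropy_bruteforce(as.numeric(1:7), sampen_params(m = 2),
                                   r_absolute = 0.5)
  expect_equal(res$B, 0)
  expect_false(res$defined)
  # r = 1: every consecutive-template pair (i, i+1) differs by exactly 1,
  # and so do all longer gaps > 1 -> pairs at gap 1 match for m and m+1;
  # gaps >= 2 have distance >= 2. Template count 5 -> 4 gap-1 pairs for
  # B; extension keeps distance 1 -> A = 4 (pairs (1,2)..(4,5) minus the
  # last which needs element 8): templates for m+1 use elements i..i+2,
  # still within 1..7 for i <= 5, so A counts gap-1 pairs of 5 templates
  res <- sample_entropy_bruteforce(as.numeric(1:7), sampen_params(m = 2),
                                   r_absolute = 1)
  expect_equal(res$B, 4)
  expect_equal(res$A, 4)
  expect_equal(res$value, 0)
})

test_that("length-3 series with m = 2 leaves a single template and no pairs", {
  res <- sample_entropy_bruteforce(c(1, 5, 2), sampen_params(m = 2))
  expect_equal(res$B, 0)
  expect_false(res$defined)
  expect_true(is.na(res$value))
})

test_that("optimized SampEn equals the brute-force oracle on random series", {
  withr::with_seed(42, {
    for (i in 1:30) {
      n <- sample(80:200, 1)
      x <- switch(1 + i %% 3,
                  rnorm(n),
                  cumsum(rnorm(n)),
                  sin(seq_len(n) / 5) + rnorm(n, sd = 0.3))
      p <- sampen_params(m = sample(1:3, 1),
                         r_coeff = sample(c(0.1, 0.2, 0.3), 1))
      a <- sample_entropy(x, p)
      b <- sample_entropy_bruteforce(x, p)
      expect_identical(a$A, b$A)
      expect_identical(a$B, b$B)
      expect_identical(a$value, b$value)
    }
  })
})

test_that("the alternative counting and comparison conventions agree with the oracle", {
  withr::with_seed(7, {
    x <- rnorm(150)
    for (tmpl in c("n-m", "n-m-1")) {
      for (mt in c("leq", "lt")) {
        p <- sampen_params(m = 2, r_coeff = 0.2, templates = tmpl,
                           match = mt)
        a <- sample_entropy(x, p)
        b <- sample_entropy_bruteforce(x, p)
        expect_identical(c(a$A, a$B), c(b$A, b$B))
      }
    }
  })
})

test_that("SampEn is exactly invariant under affine transforms", {
  withr::with_seed(3, {
    x <- rnorm(400)
    base <- sample_entropy(x)
    for (tf in list(c(2, 0), c(0.05, 3), c(-4, -1))) {
      res <- sample_entropy(tf[1] * x + tf[2])
      expect_identical(res$A, base$A)
      expect_identical(res$B, base$B)
      expect_identical(res$value, base$value)
    }
  })
})

test_that("A never exceeds B and defined values are non-negative", {
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rnorm(120)
      res <- sample_entropy(x, sampen_params(m = sample(1:3, 1)))
      expect_lte(res$A, res$B)
      if (res$defined) expect_gte(res$value, 0)
    }
  })
})

test_that("a regular sine is less entropic than white noise of equal SD", {
  t <- seq_len(3000) / 100
  sine <- sin(2 * pi * 0.7 * t)
  withr::with_seed(5, noise <- rnorm(3000, sd = sd(sine)))
  expect_lt(sample_entropy(sine)$value, sample_entropy(noise)$value)
})

test_that("SampEn of stationary synthetic series is stable from N = 6000 down to 2000", {
  sub <- generate_subject(synth_params("NLBP"), seed = 31)
  x <- trim_warmup(sub$recording)$SENS2_Gyr_Y
  full <- sample_entropy(x)$value
  short <- sample_entropy(x[1:2000])$value
  expect_lt(abs(short - full) / full, 0.10)
})

test_that("identical SENS1 and SENS2 give LCF = 0, and swapping sensors swaps the factors", {
  withr::with_seed(2, s2 <- cumsum(rnorm(800)))
  withr::with_seed(4, hip <- cumsum(rnorm(800)))
  rec <- toy_recording(800, overrides = list(
    SENS1_Gyr_Y = s2, SENS2_Gyr_Y = s2, SENS3_Gyr_Z = -hip))
  cf <- complexity_factors(rec)
  expect_equal(cf$value[cf$factor == "LCF"], 0)

  # swap thoracic and thigh roles under the stated sign conventions
  withr::with_seed(6, s1 <- cumsum(rnorm(800)))
  rec_a <- toy_recording(800, overrides = list(
    SENS1_Gyr_Y = s1, SENS2_Gyr_Y = s2, SENS3_Gyr_Z = -hip))
  rec_b <- toy_recording(800, overrides = list(
    SENS1_Gyr_Y = hip, SENS2_Gyr_Y = s2, SENS3_Gyr_Z = -s1))
  cf_a <- complexity_factors(rec_a)
  cf_b <- complexity_factors(rec_b)
  expect_equal(cf_a$value[cf_a$factor == "LCF"],
               cf_b$value[cf_b$factor == "HCF"])
  expect_equal(cf_a$value[cf_a$factor == "HCF"],
               cf_b$value[cf_b$factor == "LCF"])
})

test_that("complexity factors on contrasted presets are lower for patients", {
  cohort <- small_cohort(n = 6, seed = 11)
  cf <- purrr::map2_dfr(cohort$recording, cohort$group, function(rec, g) {
    dplyr::mutate(complexity_factors(rec), group = g)
  })
  means <- cf |>
    dplyr::group_by(factor, group) |>
    dplyr::summarise(m = mean(value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "m")
  expect_lt(means$CLBP[means$factor == "HCF"],
            means$NLBP[means$factor == "HCF"])
  expect_lt(means$CLBP[means$factor == "LCF"],
            means$NLBP[means$factor == "LCF"])
})

test_that("a missing sensor channel is a configuration error", {
  rec <- toy_recording(300)
  rec$SENS3_Gyr_Z <- NULL
  expect_error(complexity_factors(rec), class = "br_config_error")
})
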