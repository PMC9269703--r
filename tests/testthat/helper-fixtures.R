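# Shared fixtures, all generated in code.

# minimal valid recording data frame: every channel a given series
flat_recording_data <- function(n, fs = 100, value = 0) {
  cols <- c(list(time = (seq_len(n) - 1) / fs),
            setNames(rep(list(rep(value, n)), 18),
                     bendr:::channel_columns()))
  tibble::as_tibble(cols)
}

# recording whose channels can be overridden by name
toy_recording <- function(n = 1000, fs = 100, overrides = list(),
                          group = "NLBP") {
  df <- flat_recording_data(n, fs)
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  br_recording(df, subject_id = "T1", group = group, fs = fs)
}

# feature table with planted class structure: `shift` on the first
# `n_informative` features, remaining features pure noise
toy_feature_table <- function(n_per_group = 20, n_noise = 2,
                              n_informative = 1, shift = 3, seed = 1,
                              labels = c("NLBP", "CLBP")) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    tbl <- tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n)),
      group = rep(labels, each = n_per_group))
    for (j in seq_len(n_informative)) {
      tbl[[sprintf("signal%d", j)]] <-
        c(rnorm(n_per_group, 0), rnorm(n_per_group, shift))
    }
    for (j in seq_len(n_noise)) {
      tbl[[sprintf("noise%d", j)]] <- rnorm(n)
    }
    feats <- setdiff(names(tbl), c("subject_id", "group"))
    structure(tbl, feature_names = feats,
              class = c("br_features", class(tbl)))
  })
}

# small contrasted cohort, trimmed, cached across tests
small_cohort <- local({
  cache <- list()
  function(n = 6, seed = 11) {
    key <- sprintf("%d_%d", n, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- trim_cohort(generate_cohort(n = n, seed = seed))
    }
    cache[[key]]
  }
})

# the full-size study cohort used by the acceptance checks
study_cohort <- local({
  cache <- list()
  function(preset = c("paper-like", "null"), seed = 1) {
    preset <- match.arg(preset)
    key <- sprintf("%s_%d", preset, seed)
    if (is.null(cache[[key]])) {
      p_clbp <- if (preset == "paper-like") synth_params("CLBP")
                else synth_params("NLBP")
      cache[[key]] <<- trim_cohort(
        generate_cohort(synth_params("NLBP"), p_clbp, n = 20, seed = seed))
    }
    cache[[key]]
  }
})

# write a delimited recording file with canonical column names
write_canonical_file <- function(path, n = 200, fs = 100) {
  df <- flat_recording_data(n, fs)
  for (nm in bendr:::channel_columns()) df[[nm]] <- rnorm(n)
  readr::write_csv(df, path, progress = FALSE)
  df
}
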