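# Statistical describers and feature-table assembly.

.describers <- c("max", "min", "mean", "median", "Q1", "Q3", "SD")

#' Seven statistical describers of a series
#'
#' Computes the raw-data features used as classifier inputs: maximum,
#' minimum, mean, median, 1st quartile, 3rd quartile and SD. Quartiles use
#' linear interpolation between order statistics.
#'
#' @param x Numeric series of length >= 2.
#' @return A one-row tibble with columns `max`, `min`, `mean`, `median`,
#'   `Q1`, `Q3`, `SD`.
#' @export
describe_series <- function(x) {
  if (length(x) < 2) abort("need at least 2 samples (SD undefined)",
                           class = "br_insufficient_data")
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(max = max(x), min = min(x), mean = mean(x),
                 median = q[2], Q1 = q[1], Q3 = q[3], SD = sd(x))
}

#' Build a participant- or cycle-level feature table
#'
#' Assembles the feature matrix the classifier benchmark consumes. In
#' `"whole"` mode each row is one participant and every feature is a
#' describer of a full-window channel; in `"cycle"` mode recordings are
#' first segmented ([segment_cycles()]) and length-normalized
#' ([normalize_cycles()]) and each row is one cycle. Feature columns are
#' named `"<Type> <Axis> <SENSOR> <describer>"` (e.g. `"Gyr Y SENS2 min"`).
#'
#' Feature sets, following the study's three configurations:
#' * `"raw"` — 7 describers of each recorded channel (18 channels x 7 =
#'   126 features with the default channel set);
#' * `"sampen"` — SampEn of each recorded channel (18 features, named
#'   `"SampEn <Type> <Axis> <SENSOR>"`); whole mode only;
#' * `"cf"` — the two complexity factors `LCF` and `HCF`; whole mode only.
#'
#' Undefined SampEn values propagate as `NA`.
#'
#' @param cohort A tibble with columns `subject_id`, `group` and a
#'   `recording` list-column of trimmed [br_recording()] objects (the
#'   layout produced by [generate_cohort()]).
#' @param mode `"whole"` (default) or `"cycle"`.
#' @param feature_set Character subset of `c("raw", "sampen", "cf")`;
#'   sets are concatenated in the given order.
#' @param include_derived Also include describers of the derived `AccA`
#'   and `AngC` channels (raw set, whole mode; default `FALSE`).
#' @param sampen A [sampen_params()] object for SampEn/CF columns.
#' @param segmentation A [segmentation_params()] object (cycle mode).
#' @return A `br_features` tibble: `subject_id`, `group`, (`cycle` in
#'   cycle mode), then one numeric column per feature. The attribute
#'   `feature_names` lists the feature columns.
#' @export
build_feature_table <- function(cohort,
                                mode = c("whole", "cycle"),
                                feature_set = "raw",
                                include_derived = FALSE,
                                sampen = sampen_params(),
                                segmentation = segmentation_params()) {
  mode <- match.arg(mode)
  stopifnot(all(feature_set %in% c("raw", "sampen", "cf")),
            length(feature_set) >= 1)
  if (mode == "cycle" && !identical(feature_set, "raw")) {
    abort("cycle mode supports the raw feature set only",
          class = "br_config_error")
  }
  types <- if (include_derived) c(.recorded_types, .derived_types) else .recorded_types
  chans <- channel_columns(types)
  rows <- purrr::pmap(cohort[c("subject_id", "group", "recording")],
                      function(subject_id, group, recording) {
    if (mode == "whole") {
      parts <- list()
      if ("raw" %in% feature_set) {
        parts <- c(parts, list(describe_channels(recording, chans)))
      }
      if ("sampen" %in% feature_set) {
        se <- channel_entropy(recording, sampen)
        parts <- c(parts, list(tibble::as_tibble(
          setNames(as.list(se$value), paste("SampEn", se$channel)))))
      }
      if ("cf" %in% feature_set) {
        cf <- complexity_factors(recording, sampen)
        parts <- c(parts, list(tibble::tibble(LCF = cf$value[1],
                                              HCF = cf$value[2])))
      }
      dplyr::bind_cols(tibble::tibble(subject_id = subject_id, group = group),
                       !!!parts)
    } else {
      cyc <- segment_recording(recording, segmentation, chans)
      per_cycle <- cyc |>
        dplyr::group_by(.data$cycle) |>
        dplyr::group_modify(~ describe_channels_df(.x, chans)) |>
        dplyr::ungroup()
      dplyr::bind_cols(
        tibble::tibble(subject_id = subject_id, group = group,
                       cycle = per_cycle$cycle),
        per_cycle[, setdiff(names(per_cycle), "cycle")])
    }
  })
  out <- dplyr::bind_rows(rows)
  meta <- intersect(c("subject_id", "group", "cycle"), names(out))
  structure(out, feature_names = setdiff(names(out), meta),
            class = c("br_features", class(out)))
}

describe_channels <- function(rec, chans) {
  describe_channels_df(tibble::as_tibble(rec)[, chans, drop = FALSE], chans)
}

describe_channels_df <- function(df, chans) {
  cols <- purrr::imap(df[chans], function(v, ch) {
    d <- describe_series(v)
    setNames(as.list(d), paste(channel_display(ch), names(d)))
  })
  tibble::as_tibble(purrr::flatten(cols))
}

#' @export
print.br_features <- function(x, ...) {
  cat(sprintf("<br_features> %d rows x %d features (%s)\n", nrow(x),
              length(attr(x, "feature_names")),
              if ("cycle" %in% names(x)) "cycle mode" else "whole-sequence mode"))
  NextMethod()
}

feature_names <- function(table) attr(table, "feature_names")

#' Write / read a feature table as delimited text
#'
#' @param table A `br_features` tibble.
#' @param path Output path (`.tsv` for tab-delimited).
#' @return `path` invisibly, or the re-read `br_features`.
#' @export
write_feature_table <- function(table, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(tibble::as_tibble(table), path, delim = delim,
                     progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  meta <- intersect(c("subject_id", "group", "cycle"), names(df))
  structure(df, feature_names = setdiff(names(df), meta),
            class = c("br_features", class(df)))
}
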