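# End-to-end pipeline configuration and orchestration.

#' Pipeline configuration
#'
#' All settings of the full analysis with defaults reproducing the
#' study protocol: analysis window 10-70 s, SampEn with m = 2 and
#' r = 0.2 SD, segmentation window 25 samples with a 40% threshold and
#' 450-point cycles, raw describers as features, 5-fold CV with 100
#' repetitions.
#'
#' @param data_dir Directory with a written cohort ([write_cohort()]
#'   layout); `NULL` to synthesize.
#' @param synth_preset `"paper-like"` (contrasted groups) or `"null"`
#'   (identical groups), used when `data_dir` is `NULL`.
#' @param n_subjects Subjects per group for synthetic cohorts.
#' @param t0,t1 Analysis window bounds, s.
#' @param sampen A [sampen_params()] object.
#' @param segmentation A [segmentation_params()] object.
#' @param mode Feature table mode, `"whole"` or `"cycle"`.
#' @param feature_set Feature sets to benchmark (subset of
#'   `c("raw", "sampen", "cf")`; each is benchmarked separately).
#' @param folds,repetitions,grouping CV protocol (see [eval_protocol()]).
#' @param sfs Run the sequential-feature-selection rankings (default
#'   `TRUE`; forward and backward).
#' @param out_dir Output directory for the report bundle (`NULL` = no
#'   files written).
#' @param seed Base seed for cohort generation and evaluation.
#' @return A validated `br_run_config` list.
#' @export
run_config <- function(data_dir = NULL, synth_preset = "paper-like",
                       n_subjects = 20, t0 = 10, t1 = 70,
                       sampen = sampen_params(),
                       segmentation = segmentation_params(),
                       mode = "whole", feature_set = "raw",
                       folds = 5, repetitions = 100,
                       grouping = "rowwise", sfs = TRUE,
                       out_dir = NULL, seed = 1) {
  cfg <- as.list(environment())
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$data_dir) && !dir.exists(cfg$data_dir)) {
    abort(paste0("data_dir does not exist: ", cfg$data_dir),
          class = "br_config_error")
  }
  if (is.null(cfg$data_dir) &&
      !cfg$synth_preset %in% c("paper-like", "null")) {
    abort("synth_preset must be 'paper-like' or 'null'",
          class = "br_config_error")
  }
  if (cfg$t1 <= cfg$t0) abort("t1 must exceed t0", class = "br_config_error")
  stopifnot(inherits(cfg$sampen, "br_sampen_params"),
            inherits(cfg$segmentation, "br_segmentation_params"))
  if (!cfg$mode %in% c("whole", "cycle")) {
    abort("mode must be 'whole' or 'cycle'", class = "br_config_error")
  }
  if (!all(cfg$feature_set %in% c("raw", "sampen", "cf"))) {
    abort("feature_set entries must be in raw/sampen/cf",
          class = "br_config_error")
  }
  if (!cfg$grouping %in% c("rowwise", "subjectwise")) {
    abort("grouping must be 'rowwise' or 'subjectwise'",
          class = "br_config_error")
  }
  stopifnot(cfg$folds >= 2, cfg$repetitions >= 1, cfg$n_subjects >= 1)
  structure(cfg, class = "br_run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file; keys as in [run_config()], with
#'   `sampen` and `segmentation` given as nested maps of their
#'   parameters.
#' @return A validated `br_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  raw$sampen <- do.call(sampen_params, as.list(raw$sampen))
  raw$segmentation <- do.call(segmentation_params,
                              as.list(raw$segmentation))
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a cohort: trim the warm-up, derive kinematic
#' channels, compute SampEn and complexity factors with group statistics,
#' segment and normalize cycles, build feature tables, benchmark the
#' seven classifiers, and (optionally) run the SFS rankings. When
#' `out_dir` is set, writes the report bundle as delimited text (entropy
#' group table, benchmark and SFS tables, cycle dataset) plus a
#' reproducibility manifest (`manifest.json`: configuration and seeds).
#' Stage failures abort with the stage name in the error message.
#'
#' @param config A [run_config()].
#' @return A list with elements `cohort`, `entropy` (per-subject SampEn/
#'   CF values), `entropy_stats`, `cycles` (per-subject cycle counts and
#'   the pooled normalized-cycle dataset), `features`, `benchmarks` (one
#'   `br_benchmark` per feature set) and `sfs` (forward/backward
#'   `br_sfs`), invisibly also written to `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "br_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    })
  }

  cohort <- stage("load", {
    if (!is.null(config$data_dir)) {
      read_cohort(config$data_dir)
    } else if (config$synth_preset == "paper-like") {
      generate_cohort(synth_params("NLBP"), synth_params("CLBP"),
                      n = config$n_subjects, seed = config$seed)
    } else {
      generate_cohort(synth_params("NLBP"), synth_params("NLBP"),
                      n = config$n_subjects, seed = config$seed)
    }
  })
  cohort <- stage("trim", trim_cohort(cohort, config$t0, config$t1))

  entropy <- stage("sampen", {
    purrr::map2_dfr(cohort$recording, cohort$subject_id, function(rec, sid) {
      se <- channel_entropy(rec, config$sampen,
                            channel_columns("Gyr"))
      cf <- complexity_factors(rec, config$sampen)
      tibble::tibble(subject_id = sid, group = rec_group(rec),
                     !!!setNames(as.list(se$value),
                                 paste("SampEn", se$channel)),
                     LCF = cf$value[1], HCF = cf$value[2])
    })
  })
  entropy_stats <- stage("stats", entropy_group_table(entropy))

  cycles <- stage("segment", {
    sets <- purrr::map(cohort$recording, segment_recording,
                       params = config$segmentation)
    counts <- tibble::tibble(
      subject_id = cohort$subject_id, group = cohort$group,
      n_cycles = vapply(sets, function(s) max(s$cycle), numeric(1)))
    pooled <- purrr::map2_dfr(sets, cohort$subject_id, function(s, sid) {
      dplyr::mutate(tibble::as_tibble(s), subject_id = sid,
                    group = attr(s, "group"), .before = 1)
    })
    list(counts = counts, dataset = pooled)
  })

  features <- stage("features", {
    build_feature_table(cohort, mode = config$mode, feature_set = "raw",
                        sampen = config$sampen,
                        segmentation = config$segmentation)
  })

  protocol <- eval_protocol(config$folds, config$repetitions,
                            seed = config$seed, grouping = config$grouping)
  benchmarks <- stage("benchmark", {
    purrr::map(setNames(config$feature_set, config$feature_set),
               function(fset) {
      tbl <- if (fset == "raw") features else {
        build_feature_table(cohort, mode = "whole", feature_set = fset,
                            sampen = config$sampen)
      }
      evaluate_classifiers(tbl, protocol = protocol, feature_set_tag = fset)
    })
  })

  sfs <- if (isTRUE(config$sfs)) stage("sfs", {
    list(forward = sfs_rank(features, protocol = protocol,
                            direction = "forward"),
         backward = sfs_rank(features, protocol = protocol,
                             direction = "backward"))
  }) else NULL

  result <- list(cohort = cohort, entropy = entropy,
                 entropy_stats = entropy_stats, cycles = cycles,
                 features = features, benchmarks = benchmarks, sfs = sfs)
  if (!is.null(config$out_dir)) {
    stage("report", write_report_bundle(result, config))
  }
  invisible(result)
}

write_report_bundle <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  readr::write_csv(result$entropy, p("entropy_values.csv"), progress = FALSE)
  readr::write_csv(result$entropy_stats, p("entropy_group_table.csv"),
                   progress = FALSE)
  readr::write_csv(result$cycles$counts, p("cycle_counts.csv"),
                   progress = FALSE)
  cyc_long <- result$cycles$dataset |>
    tidyr::pivot_longer(-dplyr::all_of(c("subject_id", "group", "cycle",
                                         "itime")),
                        names_to = "channel", values_to = "value")
  readr::write_csv(cyc_long, p("cycle_dataset.csv"), progress = FALSE)
  purrr::iwalk(result$benchmarks, function(b, tag) {
    readr::write_csv(tidy(b), p(sprintf("benchmark_%s.csv", tag)),
                     progress = FALSE)
  })
  if (!is.null(result$sfs)) {
    purrr::iwalk(result$sfs, function(s, dirn) {
      readr::write_csv(tibble::as_tibble(s), p(sprintf("sfs_%s.csv", dirn)),
                       progress = FALSE)
    })
  }
  manifest <- list(
    config = config_to_list(config),
    subjects = dplyr::select(tibble::as_tibble(result$cohort),
                             dplyr::any_of(c("subject_id", "group", "seed"))),
    package_version = as.character(utils::packageVersion("bendr")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$out_dir)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$sampen <- unclass(out$sampen)
  out$segmentation <- unclass(out$segmentation)
  out$out_dir <- NULL     # where the bundle lives, not part of the run
  out
}
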