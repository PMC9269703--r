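# Repeated, scaled, stratified cross-validation benchmark and
# sequential feature selection.

#' Evaluation protocol
#'
#' Settings for the repeated cross-validation benchmark: per repetition
#' the rows are shuffled with a repetition-specific seed, assigned to
#' stratified folds, and per-feature standardization is fitted on the
#' training folds only. Accuracy and AUC are pooled over the held-out
#' folds of one repetition; means and SDs are taken over repetitions.
#'
#' @param folds Number of CV folds (default 5).
#' @param repetitions Number of training repetitions (default 100).
#' @param seed Base random seed; every source of randomness derives from
#'   it, so equal seeds give bit-identical results.
#' @param grouping `"rowwise"` (default; mirrors treating cycles as
#'   independent rows) or `"subjectwise"` (leakage-safe in cycle mode: no
#'   subject appears in both training and test folds).
#' @return A `br_protocol` list.
#' @export
eval_protocol <- function(folds = 5, repetitions = 100, seed = 1,
                          grouping = c("rowwise", "subjectwise")) {
  grouping <- match.arg(grouping)
  stopifnot(folds >= 2, repetitions >= 1)
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), grouping = grouping),
            class = "br_protocol")
}

# --- internals ---------------------------------------------------------

# rank-based AUC of score for the positive class (second level);
# ties get midranks (Mann-Whitney convention)
auc_score <- function(y, score, positive) {
  pos <- y == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment for shuffled data; subjectwise grouping
# assigns whole subjects (stratified by their group label) to folds
assign_folds <- function(y, folds, subject = NULL, grouping = "rowwise") {
  if (grouping == "subjectwise" && !is.null(subject)) {
    subj <- unique(subject)
    subj_y <- y[match(subj, subject)]
    f_subj <- integer(length(subj))
    for (lv in levels(y)) {
      idx <- sample(which(subj_y == lv))
      f_subj[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f_subj[match(subject, subj)]
  } else {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  }
}

scale_fit <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(mu = mu, sg = sg)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sg, "/")

features_matrix <- function(table, features = NULL) {
  if (is.null(features)) features <- feature_names(table)
  X <- as.matrix(tibble::as_tibble(table)[, features, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

# one repetition of scaled stratified CV for one spec; returns pooled
# accuracy and AUC
cv_once <- function(X, y, subject, spec, folds, grouping, f = NULL) {
  if (is.null(f)) f <- assign_folds(y, folds, subject, grouping)
  pred <- character(length(y))
  score <- numeric(length(y))
  for (k in seq_len(folds)) {
    te <- which(f == k); tr <- which(f != k)
    if (length(te) == 0) next
    if (length(unique(y[tr])) < 2) {
      warn("single-class training fold skipped")
      pred[te] <- NA_character_; score[te] <- NA_real_
      next
    }
    sc <- scale_fit(X[tr, , drop = FALSE])
    fit <- fit_classifier(spec, scale_apply(X[tr, , drop = FALSE], sc), y[tr])
    out <- score_classifier(fit, scale_apply(X[te, , drop = FALSE], sc))
    pred[te] <- out$class; score[te] <- out$score
  }
  ok <- !is.na(pred)
  c(accuracy = mean(pred[ok] == as.character(y)[ok]),
    auc = auc_score(y[ok], score[ok], levels(y)[2]))
}

table_xy <- function(table) {
  y <- factor(table$group)
  if (nlevels(y) < 2) abort("feature table has a single class",
                            class = "br_config_error")
  X <- features_matrix(table)
  if (anyNA(X)) {
    keep <- stats::complete.cases(X)
    warn(sprintf("dropping %d row(s) with missing features", sum(!keep)))
    X <- X[keep, , drop = FALSE]
    y <- droplevels(y[keep])
    subject <- table$subject_id[keep]
  } else {
    subject <- table$subject_id
  }
  list(X = X, y = y, subject = subject)
}

# --- grid search -------------------------------------------------------

#' Grid search over a classifier's hyperparameters
#'
#' Exhaustively scores every grid combination by cross-validated accuracy
#' (one fixed fold assignment drawn from the protocol seed, shared by all
#' combinations) and stores the best in `spec$selected`. Ties are broken
#' in favour of the first-listed candidate combination, candidates
#' varying fastest in the first-listed hyperparameter.
#'
#' @param table A `br_features` table with two classes.
#' @param spec A [classifier_spec()].
#' @param protocol An [eval_protocol()].
#' @return The spec with `selected` replaced; the attribute `scores`
#'   holds the full grid with CV accuracies.
#' @export
grid_search <- function(table, spec, protocol = eval_protocol()) {
  d <- table_xy(table)
  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  acc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cand <- spec
    cand$selected <- as.list(combos[i, , drop = FALSE])
    withr::with_seed(protocol$seed, {
      res <- cv_once(d$X, d$y, d$subject, cand, protocol$folds,
                     protocol$grouping)
    })
    acc[i] <- res["accuracy"]
  }
  best <- which.max(acc)   # first maximum = first-listed tie-break
  spec$selected <- as.list(combos[best, , drop = FALSE])
  attr(spec, "scores") <- dplyr::bind_cols(tibble::as_tibble(combos),
                                           tibble::tibble(accuracy = acc))
  spec
}

# --- benchmark ---------------------------------------------------------

#' Benchmark classifiers by repeated cross-validation
#'
#' Evaluates each classifier spec with `repetitions` rounds of shuffled,
#' stratified, `folds`-fold cross-validation (scaler fitted on training
#' folds only), reporting accuracy and AUC as mean and SD over
#' repetitions. Identical protocol seeds give bit-identical results.
#'
#' @param table A `br_features` table.
#' @param specs List of [classifier_spec()]s (default: all seven).
#' @param protocol An [eval_protocol()].
#' @param feature_set_tag Optional label stored with the result.
#' @return A `br_benchmark` tibble: `algorithm`, `accuracy_mean`,
#'   `accuracy_sd`, `auc_mean`, `auc_sd`; per-repetition values are kept
#'   in the `repetitions` attribute.
#' @export
evaluate_classifiers <- function(table, specs = default_classifier_specs(),
                                 protocol = eval_protocol(),
                                 feature_set_tag = NULL) {
  if (inherits(specs, "br_classifier_spec")) specs <- list(specs)
  d <- table_xy(table)
  if (nrow(d$X) < protocol$folds) {
    abort("fewer rows than folds", class = "br_config_error")
  }
  per_rep <- purrr::map(specs, function(spec) {
    reps <- matrix(NA_real_, protocol$repetitions, 2,
                   dimnames = list(NULL, c("accuracy", "auc")))
    for (r in seq_len(protocol$repetitions)) {
      withr::with_seed(protocol$seed + r, {
        reps[r, ] <- cv_once(d$X, d$y, d$subject, spec, protocol$folds,
                             protocol$grouping)
      })
    }
    reps
  })
  out <- purrr::imap_dfr(per_rep, function(reps, alg) {
    tibble::tibble(algorithm = alg,
                   accuracy_mean = mean(reps[, "accuracy"]),
                   accuracy_sd = sd(reps[, "accuracy"]),
                   auc_mean = mean(reps[, "auc"], na.rm = TRUE),
                   auc_sd = sd(reps[, "auc"], na.rm = TRUE))
  })
  structure(out, repetitions = per_rep, protocol = protocol,
            feature_set_tag = feature_set_tag,
            class = c("br_benchmark", class(out)))
}

#' @export
print.br_benchmark <- function(x, ...) {
  tag <- attr(x, "feature_set_tag")
  cat(sprintf("<br_benchmark>%s %d algorithm(s), %d repetitions\n",
              if (is.null(tag)) "" else paste0(" [", tag, "]"),
              nrow(x), attr(x, "protocol")$repetitions))
  NextMethod()
}

#' @export
tidy.br_benchmark <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(
      accuracy = sprintf("%.2f ± %.2f", .data$accuracy_mean,
                         .data$accuracy_sd),
      auc = sprintf("%.2f ± %.2f", .data$auc_mean, .data$auc_sd))
}

#' @export
glance.br_benchmark <- function(x, ...) {
  best <- which.max(x$accuracy_mean)
  tibble::tibble(best_algorithm = x$algorithm[best],
                 best_accuracy = x$accuracy_mean[best],
                 best_auc = x$auc_mean[best],
                 n_algorithms = nrow(x),
                 repetitions = attr(x, "protocol")$repetitions)
}

# --- sequential feature selection --------------------------------------

#' Sequential feature selection ranking
#'
#' Greedy wrapper selection scored by cross-validated accuracy, run once
#' per (algorithm x repetition) with repetition-specific shuffling.
#' Forward selection adds the best-scoring feature at each step, giving a
#' hierarchy from best to worst; backward elimination removes the feature
#' whose removal hurts least, ranking features by how long they survive
#' (the last survivor ranks first). The first- and second-ranked features
#' of every run are tallied.
#'
#' @param table A `br_features` table.
#' @param specs List of [classifier_spec()]s (default: all seven, giving
#'   7 x `repetitions` runs).
#' @param protocol An [eval_protocol()].
#' @param direction `"forward"` or `"backward"`.
#' @return A `br_sfs` tibble: `feature`, `first`, `second` counts over
#'   all runs (first-place counts sum to the number of runs), with
#'   attributes `total_runs` and `direction`.
#' @export
sfs_rank <- function(table, specs = default_classifier_specs(),
                     protocol = eval_protocol(),
                     direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (inherits(specs, "br_classifier_spec")) specs <- list(specs)
  d <- table_xy(table)
  feats <- feature_names(table)
  if (length(feats) < 2) abort("need at least 2 features",
                               class = "br_config_error")
  cv_acc <- function(cols, spec, f) {
    cv_once(d$X[, cols, drop = FALSE], d$y, d$subject, spec,
            protocol$folds, protocol$grouping, f = f)["accuracy"]
  }
  run_one <- function(spec) {
    # one fold assignment per run, shared by all candidate subsets
    f <- assign_folds(d$y, protocol$folds, d$subject, protocol$grouping)
    if (direction == "forward") {
      chosen <- character(0)
      remaining <- feats
      for (step in 1:2) {
        sc <- vapply(remaining, function(ft) cv_acc(c(chosen, ft), spec, f),
                     numeric(1))
        pick <- remaining[which.max(sc)]   # earliest tie wins
        chosen <- c(chosen, pick)
        remaining <- setdiff(remaining, pick)
      }
      chosen
    } else {
      remaining <- feats
      removed <- character(0)
      while (length(remaining) > 1) {
        sc <- vapply(remaining, function(ft) cv_acc(setdiff(remaining, ft),
                                                    spec, f), numeric(1))
        drop <- remaining[which.max(sc)]   # least useful feature
        remaining <- setdiff(remaining, drop)
        removed <- c(removed, drop)
      }
      c(remaining, rev(removed)[1])        # survivor first, then last-removed
    }
  }
  first <- character(0); second <- character(0)
  for (spec in specs) {
    for (r in seq_len(protocol$repetitions)) {
      withr::with_seed(protocol$seed + r, {
        top2 <- run_one(spec)
      })
      first <- c(first, top2[1]); second <- c(second, top2[2])
    }
  }
  total <- length(specs) * protocol$repetitions
  out <- tibble::tibble(feature = feats) |>
    dplyr::mutate(first = vapply(.data$feature, function(f) sum(first == f),
                                 numeric(1)),
                  second = vapply(.data$feature, function(f) sum(second == f),
                                  numeric(1))) |>
    dplyr::arrange(dplyr::desc(.data$first), dplyr::desc(.data$second))
  structure(out, total_runs = total, direction = direction,
            class = c("br_sfs", class(out)))
}

#' @export
print.br_sfs <- function(x, ...) {
  cat(sprintf("<br_sfs> %s selection, %d runs\n", attr(x, "direction"),
              attr(x, "total_runs")))
  NextMethod()
}

#' @export
glance.br_sfs <- function(x, ...) {
  tibble::tibble(top_feature = x$feature[which.max(x$first)],
                 top_first_count = max(x$first),
                 total_runs = attr(x, "total_runs"),
                 direction = attr(x, "direction"))
}
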