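# Cross-validated benchmark, grid search and SFS behaviour.

test_that("all algorithms reach perfect scores in the separable limit", {
  tbl <- toy_feature_table(n_per_group = 15, n_noise = 1,
                           n_informative = 2, shift = 8, seed = 2)
  bm <- evaluate_classifiers(tbl, protocol = eval_protocol(5, 3, seed = 1))
  expect_equal(nrow(bm), 7)
  expect_true(all(bm$accuracy_mean > 0.95))
  expect_true(all(bm$auc_mean > 0.98))
  expect_true(all(bm$accuracy_sd >= 0))
})

test_that("the same seed gives bit-identical benchmark results", {
  tbl <- toy_feature_table(n_per_group = 10, shift = 1.5, seed = 3)
  pr <- eval_protocol(4, 4, seed = 9)
  b1 <- evaluate_classifiers(tbl, protocol = pr)
  b2 <- evaluate_classifiers(tbl, protocol = pr)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  b3 <- evaluate_classifiers(tbl, protocol = eval_protocol(4, 4, seed = 10))
  expect_false(identical(as.data.frame(b1), as.data.frame(b3)))
})

test_that("permuted labels score at chance for every algorithm", {
  tbl <- toy_feature_table(n_per_group = 20, n_noise = 3, shift = 2,
                           seed = 4)
  withr::with_seed(8, tbl$group <- sample(tbl$group))
  bm <- evaluate_classifiers(tbl, protocol = eval_protocol(5, 15, seed = 2))
  expect_true(all(abs(bm$accuracy_mean - 0.5) <= 0.15))
})

test_that("standardization is fitted on training folds only", {
  # replicate one repetition's fold assignment, then compute the CV
  # predictions two ways by hand: scaler fitted on the training folds
  # (clean) and scaler fitted on all rows (leaky). The package's CV must
  # match the clean variant bit for bit, and the planted-shift fixture is
  # built so the two variants actually disagree.
  tbl <- toy_feature_table(n_per_group = 12, n_noise = 2,
                           n_informative = 2, shift = 1.2, seed = 16)
  d <- bendr:::table_xy(tbl)
  spec <- default_classifier_specs()[["BF KNN"]]
  seed <- 3
  pkg <- withr::with_seed(seed, {
    bendr:::cv_once(d$X, d$y, d$subject, spec, 4, "rowwise")
  })
  f <- withr::with_seed(seed, bendr:::assign_folds(d$y, 4))
  run_variant <- function(leaky) {
    pred <- character(length(d$y)); sc_all <- bendr:::scale_fit(d$X)
    score <- numeric(length(d$y))
    for (k in 1:4) {
      te <- which(f == k); tr <- which(f != k)
      sc <- if (leaky) sc_all else bendr:::scale_fit(d$X[tr, , drop = FALSE])
      fit <- bendr:::fit_classifier(
        spec, bendr:::scale_apply(d$X[tr, , drop = FALSE], sc), d$y[tr])
      out <- bendr:::score_classifier(
        fit, bendr:::scale_apply(d$X[te, , drop = FALSE], sc))
      pred[te] <- out$class; score[te] <- out$score
    }
    c(accuracy = mean(pred == as.character(d$y)),
      auc = bendr:::auc_score(d$y, score, levels(d$y)[2]))
  }
  clean <- run_variant(leaky = FALSE)
  leaky <- run_variant(leaky = TRUE)
  expect_identical(unname(pkg), unname(clean))
  expect_false(identical(unname(clean), unname(leaky)))
})

test_that("subject-wise grouping removes the leakage that row-wise splitting allows", {
  # cycles = identical copies of each subject's feature vector with a
  # random subject label: row-wise CV can memorize the subject, the
  # subject-wise split cannot
  withr::with_seed(12, {
    n_subj <- 16
    feat <- rnorm(n_subj)
    lab <- sample(rep(c("NLBP", "CLBP"), each = n_subj / 2))
  })
  tbl <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", seq_len(n_subj)), each = 6),
    group = rep(lab, each = 6),
    f1 = rep(feat, each = 6))
  attr(tbl, "feature_names") <- "f1"
  class(tbl) <- c("br_features", class(tbl))
  knn <- list(classifier_spec("BF KNN", selected = list(
    n_neighbors = 3, weights = "distance", algorithm = "brute")))
  b_row <- evaluate_classifiers(tbl, knn,
                                eval_protocol(4, 10, seed = 5,
                                              grouping = "rowwise"))
  b_subj <- evaluate_classifiers(tbl, knn,
                                 eval_protocol(4, 10, seed = 5,
                                               grouping = "subjectwise"))
  expect_gt(b_row$accuracy_mean, 0.95)          # pure memorization
  expect_lt(b_subj$accuracy_mean, 0.75)         # no subject leakage
})

test_that("grid search returns single candidates directly and breaks ties first-listed", {
  tbl <- toy_feature_table(n_per_group = 10, shift = 6, seed = 7)
  one <- classifier_spec("Linear SVM", grid = list(C = 0.1))
  gs <- grid_search(tbl, one, eval_protocol(3, 1, seed = 1))
  expect_equal(gs$selected$C, 0.1)
  # separable table: every moderate C reaches accuracy 1 -> the
  # first-listed of the tied maxima wins
  full <- grid_search(tbl, classifier_spec("Linear SVM",
                                           grid = list(C = c(0.1, 1, 10))),
                      eval_protocol(3, 1, seed = 1))
  scores <- attr(full, "scores")
  expect_true(all(scores$accuracy == 1))
  expect_equal(full$selected$C, 0.1)
  expect_error(grid_search(dplyr::mutate(tbl, group = "NLBP"), one),
               class = "br_config_error")
})

test_that("grid search over the study grids selects a member of each grid", {
  tbl <- toy_feature_table(n_per_group = 8, n_noise = 2, shift = 1.5,
                           seed = 8)
  pr <- eval_protocol(3, 1, seed = 2)
  for (alg in c("GaussianNB", "DT")) {
    gs <- grid_search(tbl, classifier_spec(alg), pr)
    for (h in names(gs$selected)) {
      expect_true(gs$selected[[h]] %in% gs$grid[[h]])
    }
  }
})

test_that("forward SFS recovers a planted feature and conserves counts", {
  tbl <- toy_feature_table(n_per_group = 20, n_noise = 9,
                           n_informative = 1, shift = 2.5, seed = 9)
  sf <- sfs_rank(tbl, specs = default_classifier_specs()[c("GaussianNB",
                                                           "Linear SVM")],
                 protocol = eval_protocol(5, 5, seed = 4))
  expect_equal(attr(sf, "total_runs"), 10)
  expect_equal(sum(sf$first), 10)
  expect_equal(sf$feature[1], "signal1")
  expect_gt(sf$first[1] / 10, 0.8)
})

test_that("duplicated informative features split the first places between them", {
  tbl <- toy_feature_table(n_per_group = 15, n_noise = 2,
                           n_informative = 1, shift = 4, seed = 10)
  tbl$signal2 <- tbl$signal1
  attr(tbl, "feature_names") <- c(attr(tbl, "feature_names"), "signal2")
  sf <- sfs_rank(tbl, specs = default_classifier_specs()["GaussianNB"],
                 protocol = eval_protocol(5, 8, seed = 6))
  expect_equal(sum(sf$first), 8)
  twins <- sf$feature[sf$first > 0]
  expect_true(all(twins %in% c("signal1", "signal2")))
})

test_that("backward SFS ranks the survivor first", {
  tbl <- toy_feature_table(n_per_group = 15, n_noise = 3,
                           n_informative = 1, shift = 4, seed = 11)
  sb <- sfs_rank(tbl, specs = default_classifier_specs()["GaussianNB"],
                 protocol = eval_protocol(5, 5, seed = 7),
                 direction = "backward")
  expect_equal(attr(sb, "direction"), "backward")
  expect_equal(sum(sb$first), 5)
  expect_equal(sb$feature[1], "signal1")
})

test_that("single-class tables and single-feature SFS are rejected", {
  tbl <- toy_feature_table(n_per_group = 5, seed = 12)
  tbl1 <- tbl
  attr(tbl1, "feature_names") <- "signal1"
  expect_error(sfs_rank(tbl1), class = "br_config_error")
  tbl$group <- "NLBP"
  expect_error(evaluate_classifiers(tbl), class = "br_config_error")
})
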