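# The seven benchmark classifiers behind a uniform fit/score interface.
#
# Each classifier is fitted on a numeric matrix X (rows = observations)
# and a two-level factor y, and must return, for new rows, both a class
# prediction and a continuous score for the positive class (second factor
# level): class probabilities where the model provides them, decision
# values otherwise (SVM). KNN, Gaussian naive Bayes and AdaBoost are
# implemented here; SVMs use e1071, decision trees rpart, random forests
# ranger.

#' Classifier specification
#'
#' Bundles one of the seven benchmark algorithms with its hyperparameter
#' grid and the currently selected values. [default_classifier_specs()]
#' returns all seven with the study's grids and selected values;
#' [grid_search()] re-selects from the grid.
#'
#' @param algorithm One of `"BF KNN"`, `"Linear SVM"`, `"SVM RBF"`,
#'   `"DT"`, `"RF"`, `"AdaBoost"`, `"GaussianNB"`.
#' @param grid Named list of candidate vectors (default: the study grid
#'   for the algorithm).
#' @param selected Named list of chosen values (default: the study's
#'   grid-search selections, i.e. the first-listed... see
#'   [default_classifier_specs()]).
#' @return A `br_classifier_spec` list.
#' @export
classifier_spec <- function(algorithm, grid = NULL, selected = NULL) {
  defaults <- default_grids()
  if (!algorithm %in% names(defaults)) {
    abort(paste0("unknown algorithm: ", algorithm), class = "br_config_error")
  }
  if (is.null(grid)) grid <- defaults[[algorithm]]$grid
  if (is.null(selected)) {
    # study selection where the grid allows it, first candidate otherwise
    selected <- purrr::imap(grid, function(cand, h) {
      stud <- defaults[[algorithm]]$selected[[h]]
      if (!is.null(stud) && stud %in% cand) stud else cand[1]
    })
  }
  bad <- names(selected)[!purrr::map2_lgl(selected, grid[names(selected)],
                                          ~ .x %in% .y)]
  if (length(bad) > 0) {
    abort(paste0("selected value outside grid for: ",
                 paste(bad, collapse = ", ")), class = "br_config_error")
  }
  structure(list(algorithm = algorithm, grid = grid, selected = selected),
            class = "br_classifier_spec")
}

default_grids <- function() {
  list(
    "BF KNN" = list(
      grid = list(n_neighbors = c(3, 5, 8, 10),
                  weights = c("distance", "uniform"),
                  algorithm = c("brute", "kd_tree", "auto", "ball_tree")),
      selected = list(n_neighbors = 3, weights = "distance",
                      algorithm = "brute")),
    "Linear SVM" = list(
      grid = list(C = c(0.001, 0.01, 0.1, 1, 10, 100, 1000)),
      selected = list(C = 0.001)),
    "SVM RBF" = list(
      grid = list(C = c(0.001, 0.01, 0.1, 1, 10, 100),
                  gamma = c(0.001, 0.01, 0.1, 1, 10, 100)),
      selected = list(C = 1, gamma = 0.001)),
    "DT" = list(
      grid = list(max_depth = c(1, 5, 10, 100),
                  criterion = c("gini", "entropy"),
                  splitter = c("best", "random")),
      selected = list(max_depth = 10, criterion = "gini", splitter = "best")),
    "RF" = list(
      grid = list(max_depth = c(1, 5, 10, 100),
                  n_estimators = c(1, 5, 10, 100),
                  max_features = c(1, 5, 10, 100)),
      selected = list(max_depth = 10, n_estimators = 100, max_features = 1)),
    "AdaBoost" = list(
      grid = list(n_estimators = c(5, 10, 50, 100, 500),
                  learning_rate = c(0.000001, 0.001, 0.1, 1, 5, 10, 100)),
      selected = list(n_estimators = 50, learning_rate = 1)),
    "GaussianNB" = list(
      grid = list(var_smoothing = c(0.0000001, 0.01, 1, 10, 100)),
      selected = list(var_smoothing = 0.0000001)))
}

#' The seven benchmark classifiers with the study defaults
#'
#' Grids: KNN neighbours (3, 5, 8, 10) x weighting (distance, uniform) x
#' search strategy; Linear SVM C in 10^(-3..3); RBF SVM C x gamma;
#' decision-tree depth x split criterion x split strategy; random-forest
#' depth x trees x features-per-split; AdaBoost estimators x learning
#' rate; GaussianNB variance-smoothing ratio. The default `selected`
#' values are the grid-search picks reported by the study (KNN k = 3,
#' distance, brute; Linear SVM C = 0.001; RBF C = 1, gamma = 0.001; DT
#' depth 10, gini, best; RF depth 10, 100 trees, 1 feature; AdaBoost 50
#' estimators, rate 1; GaussianNB smoothing 1e-7).
#'
#' @return Named list of seven [classifier_spec()] objects.
#' @export
default_classifier_specs <- function() {
  algs <- names(default_grids())
  setNames(lapply(algs, classifier_spec), algs)
}

# --- uniform fit/score interface ---------------------------------------

fit_classifier <- function(spec, X, y) {
  p <- spec$selected
  alg <- spec$algorithm
  model <- switch(alg,
    "BF KNN" = list(X = X, y = y, k = p$n_neighbors, weights = p$weights),
    "Linear SVM" = e1071::svm(X, y, kernel = "linear", cost = p$C,
                              scale = FALSE),
    "SVM RBF" = e1071::svm(X, y, kernel = "radial", cost = p$C,
                           gamma = p$gamma, scale = FALSE),
    "DT" = fit_rpart(X, y, p$max_depth, p$criterion),
    "RF" = fit_ranger(X, y, p),
    "AdaBoost" = fit_adaboost(X, y, p$n_estimators, p$learning_rate),
    "GaussianNB" = fit_gnb(X, y, p$var_smoothing),
    abort(paste0("unknown algorithm: ", alg), class = "br_config_error"))
  structure(list(algorithm = alg, model = model, levels = levels(y)),
            class = "br_classifier_fit")
}

# class prediction + positive-class score (probability or decision value)
score_classifier <- function(fit, X) {
  lv <- fit$levels
  pos <- lv[2]
  switch(fit$algorithm,
    "BF KNN" = predict_knn(fit$model, X, pos),
    "Linear SVM" = ,
    "SVM RBF" = {
      pr <- predict(fit$model, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 labels the decision value "<A>/<B>": positive favours A
      score <- if (grepl(paste0("^", pos, "/"), colnames(dv)[1])) dv[, 1] else -dv[, 1]
      list(class = as.character(pr), score = unname(score))
    },
    "DT" = {
      pb <- predict(fit$model, as.data.frame(X), type = "prob")
      list(class = lv[max.col(pb[, lv, drop = FALSE])],
           score = unname(pb[, pos]))
    },
    "RF" = {
      pb <- predict(fit$model, data = as.data.frame(X),
                    num.threads = 1)$predictions
      list(class = lv[max.col(pb[, lv, drop = FALSE])],
           score = unname(pb[, pos]))
    },
    "AdaBoost" = predict_adaboost(fit$model, X, lv),
    "GaussianNB" = predict_gnb(fit$model, X, lv))
}

fit_rpart <- function(X, y, max_depth, criterion) {
  df <- as.data.frame(X)
  df$.y <- y
  split <- if (criterion == "entropy") "information" else "gini"
  rpart::rpart(.y ~ ., data = df, method = "class",
               parms = list(split = split),
               control = rpart::rpart.control(
                 maxdepth = min(max_depth, 30), minsplit = 2, cp = 0,
                 xval = 0))
}

fit_ranger <- function(X, y, p) {
  ranger::ranger(x = as.data.frame(X), y = y, num.trees = p$n_estimators,
                 mtry = min(p$max_features, ncol(X)),
                 max.depth = p$max_depth, probability = TRUE,
                 num.threads = 1,
                 seed = sample.int(.Machine$integer.max, 1))
}

# --- brute-force KNN ---------------------------------------------------

predict_knn <- function(model, X, pos) {
  tr <- as.matrix(model$X); te <- as.matrix(X)
  # squared euclidean distances test x train
  d2 <- outer(rowSums(te^2), rowSums(tr^2), "+") - 2 * te %*% t(tr)
  d <- sqrt(pmax(d2, 0))
  k <- min(model$k, nrow(tr))
  lv <- levels(model$y)
  res <- apply(d, 1, function(di) {
    nn <- order(di)[seq_len(k)]
    w <- if (model$weights == "distance") {
      dn <- di[nn]
      if (any(dn == 0)) as.numeric(dn == 0) else 1 / dn
    } else rep(1, k)
    votes <- vapply(lv, function(l) sum(w[model$y[nn] == l]), numeric(1))
    c(which.max(votes), votes[2] / sum(votes))
  })
  list(class = lv[res[1, ]], score = unname(res[2, ]))
}

# --- Gaussian naive Bayes ----------------------------------------------

fit_gnb <- function(X, y, var_smoothing) {
  X <- as.matrix(X)
  lv <- levels(y)
  stats_by <- lapply(lv, function(l) {
    Xi <- X[y == l, , drop = FALSE]
    v <- apply(Xi, 2, function(col) mean((col - mean(col))^2))  # ML variance
    list(mu = colMeans(Xi), var = v, prior = nrow(Xi) / nrow(X))
  })
  names(stats_by) <- lv
  # smoothing: ratio of the largest feature variance, added to all
  eps <- var_smoothing * max(apply(X, 2, function(col) mean((col - mean(col))^2)))
  for (l in lv) stats_by[[l]]$var <- stats_by[[l]]$var + eps
  stats_by
}

predict_gnb <- function(model, X, lv) {
  X <- as.matrix(X)
  ll <- vapply(lv, function(l) {
    m <- model[[l]]
    rowSums(dnorm(X, rep(m$mu, each = nrow(X)),
                  rep(sqrt(m$var), each = nrow(X)), log = TRUE)) +
      log(m$prior)
  }, numeric(nrow(X)))
  ll <- matrix(ll, ncol = length(lv))
  # stable posterior for the positive class
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  list(class = lv[max.col(ll)], score = post[, 2])
}

# --- AdaBoost (SAMME with decision stumps) -----------------------------

# weighted best stump over all features: threshold + polarity
fit_stump <- function(X, y01, w) {
  best <- list(err = Inf)
  for (f in seq_len(ncol(X))) {
    ord <- order(X[, f])
    xv <- X[ord, f]; yv <- y01[ord]; wv <- w[ord]
    # err(th) for rule "predict 1 when x > th", thresholds between samples
    cum_pos <- cumsum(wv * (yv == 1))   # positives predicted 0 (missed)
    cum_neg <- cumsum(wv * (yv == 0))
    tot_pos <- sum(wv * (yv == 1)); tot_neg <- sum(wv * (yv == 0))
    # after position i: left = 1..i predicted 0, right predicted 1
    err_gt <- cum_pos + (tot_neg - cum_neg)
    err_le <- cum_neg + (tot_pos - cum_pos)  # flipped polarity
    # candidate cuts only between distinct values
    valid <- which(xv[-length(xv)] < xv[-1])
    if (length(valid) == 0) next
    for (pol in c("gt", "le")) {
      e <- if (pol == "gt") err_gt else err_le
      i <- valid[which.min(e[valid])]
      if (e[i] < best$err) {
        best <- list(err = e[i], feature = f,
                     threshold = (xv[i] + xv[i + 1]) / 2, polarity = pol)
      }
    }
  }
  best
}

predict_stump <- function(stump, X) {
  x <- X[, stump$feature]
  if (stump$polarity == "gt") as.integer(x > stump$threshold)
  else as.integer(x <= stump$threshold)
}

fit_adaboost <- function(X, y, n_estimators, learning_rate) {
  X <- as.matrix(X)
  y01 <- as.integer(y) - 1L
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (b in seq_len(n_estimators)) {
    st <- fit_stump(X, y01, w)
    if (!is.finite(st$err)) break
    pred <- predict_stump(st, X)
    err <- sum(w * (pred != y01)) / sum(w)
    if (err <= 1e-10) {           # perfect stump: use it alone and stop
      stumps <- c(stumps, list(st)); alphas <- c(alphas, 1)
      break
    }
    if (err >= 0.5) break         # no better than chance: stop boosting
    alpha <- learning_rate * log((1 - err) / err)
    stumps <- c(stumps, list(st)); alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y01))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {      # degenerate: constant majority vote
    maj <- as.integer(mean(y01) >= 0.5)
    return(list(stumps = list(), alphas = numeric(0), majority = maj))
  }
  list(stumps = stumps, alphas = alphas, majority = NULL)
}

predict_adaboost <- function(model, X, lv) {
  X <- as.matrix(X)
  if (length(model$stumps) == 0) {
    cls <- lv[model$majority + 1L]
    return(list(class = rep(cls, nrow(X)), score = rep(0.5, nrow(X))))
  }
  votes <- vapply(seq_along(model$stumps), function(b) {
    model$alphas[b] * (2 * predict_stump(model$stumps[[b]], X) - 1)
  }, numeric(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  margin <- rowSums(votes) / sum(abs(model$alphas))
  list(class = lv[as.integer(margin > 0) + 1L], score = margin)
}
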