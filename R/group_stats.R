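# Group comparison and measurement-difference statistics.

#' Compare a scalar outcome between two groups
#'
#' Runs the test-selection protocol used for the entropy outcomes: each
#' group is checked for normality with a Shapiro-Wilk test; when both
#' groups pass at level `alpha`, a pooled two-sample t-test is used and
#' the descriptives reported are mean/SD/SEM; otherwise a Mann-Whitney
#' rank-sum test is used and the descriptives are median and quartiles.
#' Tests are two-sided.
#'
#' @param data A data frame with one value column and one group column.
#' @param value,group Column names (tidyselect-style, unquoted or
#'   character) of the outcome and the two-level group label.
#' @param alpha Significance level for the normality gate (default 0.05).
#' @return A `br_group_comparison` object; see [tidy.br_group_comparison()].
#' @export
compare_groups <- function(data, value, group = "group", alpha = 0.05) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  v <- data[[value]]
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2) abort("group column must have exactly 2 levels",
                             class = "br_config_error")
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  compare_groups_impl(a, b, levels(g), alpha)
}

compare_groups_impl <- function(a, b, levels, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs at least 3 observations",
          class = "br_insufficient_data")
  }
  norm_p <- c(shapiro.test(a)$p.value, shapiro.test(b)$p.value)
  normal <- all(norm_p >= alpha)
  if (normal) {
    ht <- t.test(a, b, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    test <- "Mann-Whitney"
  }
  desc <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(n = length(x), mean = mean(x), sd = sd(x),
         sem = sd(x) / sqrt(length(x)),
         median = q[2], Q1 = q[1], Q3 = q[3])
  }
  structure(list(levels = levels, a = desc(a), b = desc(b),
                 test = test, p_value = ht$p.value,
                 normality_p = setNames(norm_p, levels),
                 alpha = alpha),
            class = "br_group_comparison")
}

#' @export
print.br_group_comparison <- function(x, ...) {
  cat(sprintf("<br_group_comparison> %s vs %s: %s test, p = %.4g\n",
              x$levels[1], x$levels[2], x$test, x$p_value))
  invisible(x)
}

#' Tidy a group comparison
#'
#' One row per group with the descriptives in the style the chosen test
#' dictates (mean/SD/SEM for t; median/Q1/Q3 for Mann-Whitney), plus the
#' test name and p-value.
#'
#' @param x A `br_group_comparison`.
#' @param ... Unused.
#' @return A tibble with two rows.
#' @export
tidy.br_group_comparison <- function(x, ...) {
  row <- function(lvl, d, np) {
    base <- tibble::tibble(group = lvl, n = d$n, test = x$test,
                           p_value = x$p_value, normality_p = np)
    if (x$test == "t") {
      dplyr::bind_cols(base, tibble::tibble(mean = d$mean, sd = d$sd,
                                            sem = d$sem))
    } else {
      dplyr::bind_cols(base, tibble::tibble(median = d$median, Q1 = d$Q1,
                                            Q3 = d$Q3))
    }
  }
  dplyr::bind_rows(row(x$levels[1], x$a, x$normality_p[1]),
                   row(x$levels[2], x$b, x$normality_p[2]))
}

#' SEM, confidence interval and minimal detectable change
#'
#' Measurement-difference statistics for a between-group difference with
#' standard deviation `sd_diff` and per-group sample size `n`:
#' SEM = SD/sqrt(N); the 95% confidence interval half-width
#' CI = 1.96 * SEM; and the minimal detectable change
#' MDC = 1.96 * sqrt(2) * SEM. MDC/CI = sqrt(2) exactly.
#'
#' The 1.96 normal quantile is used (not a t quantile), matching the
#' reporting convention of the reliability literature.
#'
#' @param sd_diff SD of the between-group difference (>= 0).
#' @param n Per-group sample size (>= 2).
#' @return A one-row tibble with columns `sem`, `ci` and `mdc`.
#' @export
difference_metrics <- function(sd_diff, n) {
  stopifnot(sd_diff >= 0, n >= 2)
  sem <- sd_diff / sqrt(n)
  tibble::tibble(sem = sem, ci = 1.96 * sem, mdc = 1.96 * sqrt(2) * sem)
}

#' Group comparison table for entropy outcomes
#'
#' Applies [compare_groups()] and [difference_metrics()] to each of a set
#' of per-participant scalar outcome columns (SampEn channels, LCF, HCF),
#' producing a report shaped like the study's significance table.
#'
#' The "difference" block treats the two groups as matched pairs (the
#' study design matched each patient with a healthy subject): values are
#' paired by row order within group, and the mean and SD of the per-pair
#' NLBP - CLBP differences feed [difference_metrics()].
#'
#' @param data A data frame with a `group` column (levels CLBP/NLBP) and
#'   one column per outcome.
#' @param outcomes Character vector of outcome column names (default: all
#'   numeric columns except metadata).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per outcome: the test used, p-value,
#'   and `diff_mean`, `diff_sd`, `sem`, `ci`, `mdc` of the matched
#'   between-group difference.
#' @export
entropy_group_table <- function(data, outcomes = NULL, alpha = 0.05) {
  if (is.null(outcomes)) {
    meta <- c("subject_id", "group", "cycle")
    outcomes <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        meta)
  }
  g <- as.factor(data$group)
  lv <- levels(g)
  # orient the difference as NLBP - CLBP when those labels are present
  pos <- if (all(c("CLBP", "NLBP") %in% lv)) "NLBP" else lv[2]
  neg <- setdiff(lv, pos)[1]
  purrr::map_dfr(outcomes, function(oc) {
    a <- data[[oc]][g == neg]
    b <- data[[oc]][g == pos]
    cmp <- compare_groups_impl(a[!is.na(a)], b[!is.na(b)], c(neg, pos),
                               alpha)
    n <- min(length(a), length(b))
    d <- b[seq_len(n)] - a[seq_len(n)]
    dm <- difference_metrics(sd(d, na.rm = TRUE), sum(!is.na(d)))
    tibble::tibble(outcome = oc, test = cmp$test, p_value = cmp$p_value,
                   diff_mean = mean(d, na.rm = TRUE),
                   diff_sd = sd(d, na.rm = TRUE),
                   sem = dm$sem, ci = dm$ci, mdc = dm$mdc)
  })
}
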