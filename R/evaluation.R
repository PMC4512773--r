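.truth_frame <- function(truth) {
  if (inherits(truth, "synthetic_dataset")) truth <- truth$truth
  stopifnot(is.data.frame(truth),
            all(c("feature_id", "group_id", "is_positive") %in% names(truth)))
  truth
}

#' Score a selected feature list against ground truth
#'
#' Walks the selection in rank order and counts, among the selected
#' positives, those whose marker group already has an earlier selected
#' representative — the redundant features. The rates are
#' \deqn{\mathrm{redundancy} = \frac{\#\,\mathrm{redundant}}{\#\,\mathrm{selected}} \times 100\%,
#'   \qquad \mathrm{non\text{-}redundancy} = 100\% - \mathrm{redundancy},}
#' and the error rate is the percentage of selected features that are
#' negative markers. Negatives are counted only by the error rate, never
#' as redundant.
#'
#' @param selected Character vector of selected feature ids, in rank order.
#' @param truth Ground-truth data frame (`feature_id`, `group_id`,
#'   `is_positive`) or a `synthetic_dataset`.
#' @return An `evaluation_report` list: `n_selected`, `redundancy_rate`,
#'   `non_redundancy_rate`, `error_rate` (percent), `positive_count`,
#'   `unique_positive_groups`.
#' @export
score_selection <- function(selected, truth) {
  truth <- .truth_frame(truth)
  if (!length(selected)) stop("`selected` must be non-empty")
  idx <- match(selected, truth$feature_id)
  if (anyNA(idx)) {
    stop("selected feature(s) not in ground truth: ",
         paste(selected[is.na(idx)], collapse = ", "))
  }
  pos <- truth$is_positive[idx]
  grp <- truth$group_id[idx]
  redundant <- pos & duplicated(grp)
  n <- length(selected)
  red_rate <- 100 * sum(redundant) / n
  structure(list(n_selected = n,
                 redundancy_rate = red_rate,
                 non_redundancy_rate = 100 - red_rate,
                 error_rate = 100 * sum(!pos) / n,
                 positive_count = sum(pos),
                 unique_positive_groups = length(unique(grp[pos]))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("evaluation_report: %d selected | non-redundancy %.1f%% | ",
                     "error %.1f%% | %d positive (%d groups)\n"),
              x$n_selected, x$non_redundancy_rate, x$error_rate,
              x$positive_count, x$unique_positive_groups))
  invisible(x)
}

#' Count ground-truth positive markers in a selection
#'
#' @inheritParams score_selection
#' @return Integer count of selected features flagged positive.
#' @export
count_positive <- function(selected, truth) {
  score_selection(selected, truth)$positive_count
}

#' Rank features by the two-sided Wilcoxon rank-sum test
#'
#' The bottom-up comparator: each feature is tested between the two
#' classes with the two-sided rank-sum test (normal approximation with tie
#' and continuity corrections) and the `k` smallest-p features are
#' returned, ties resolved by input order. Constant features get p = 1.
#'
#' @param table An `abundance_table`.
#' @param metadata Paired sample metadata with exactly two classes, each
#'   with at least two samples.
#' @param k Number of features to return.
#' @return Data frame `feature_id`, `p_value`, ascending in p.
#' @export
wilcoxon_select <- function(table, metadata, k) {
  stopifnot(inherits(table, "abundance_table"))
  metadata <- sample_metadata(metadata, table)
  cls <- unique(metadata$class)
  if (length(cls) != 2) stop("wilcoxon_select needs exactly two classes")
  g1 <- metadata$class == cls[1]
  g2 <- metadata$class == cls[2]
  if (sum(g1) < 2 || sum(g2) < 2) stop("each class needs at least two samples")
  if (k > nrow(table$values)) stop("`k` exceeds the number of features")
  p <- apply(table$values, 1, function(v) {
    if (max(v) == min(v)) return(1)
    suppressWarnings(stats::wilcox.test(v[g1], v[g2], alternative = "two.sided",
                                        exact = FALSE, correct = TRUE)$p.value)
  })
  ord <- order(p, seq_along(p))[seq_len(k)]
  data.frame(feature_id = feature_ids(table)[ord], p_value = p[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-validated RBF-SVM accuracy of a feature subset
#'
#' Restricts the table to the selected features and estimates
#' classification accuracy by stratified k-fold cross-validation:
#' \deqn{\mathrm{accuracy} = \frac{\#\,\mathrm{correctly\ classified}}{\#\,\mathrm{test\ samples}} \times 100\%.}
#' Within each outer fold, features are min-max scaled to \[-1, 1\] using
#' the training data only, and the RBF-SVM cost and gamma are chosen by an
#' inner cross-validated grid search on the training fold (the customary
#' log2-spaced grids of the LIBSVM easy.py protocol).
#'
#' @param table An `abundance_table`.
#' @param selected Feature ids to classify with.
#' @param metadata Paired sample metadata (two classes).
#' @param folds Number of outer folds (default 6).
#' @param seed Seed for the fold assignment.
#' @param cost_grid,gamma_grid Hyperparameter grids.
#' @param inner_folds Folds of the inner model-selection CV.
#' @return Mean accuracy in percent, with per-fold accuracies in
#'   attribute `"fold_accuracy"`.
#' @export
svm_cv_accuracy <- function(table, selected, metadata, folds = 6, seed = 1,
                            cost_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2),
                            inner_folds = 5) {
  stopifnot(inherits(table, "abundance_table"))
  metadata <- sample_metadata(metadata, table)
  idx <- match(selected, feature_ids(table))
  if (anyNA(idx)) stop("selected feature(s) not in table")
  x <- t(table$values[idx, , drop = FALSE])
  y <- factor(metadata$class)
  if (nlevels(y) != 2) stop("classification needs exactly two classes")
  if (folds < 2) stop("`folds` must be >= 2")
  if (min(table(y)) < folds) stop("fold count exceeds the smaller class size")

  fold_of <- integer(length(y))
  with_seed(seed, for (lv in levels(y)) {
    members <- which(y == lv)
    fold_of[members] <- sample(rep_len(seq_len(folds), length(members)))
  })

  scale01 <- function(train, test) {
    lo <- apply(train, 2, min)
    hi <- apply(train, 2, max)
    rng <- ifelse(hi > lo, hi - lo, 1)
    sc <- function(m) sweep(sweep(m, 2, lo), 2, rng, "/") * 2 - 1
    list(train = sc(train), test = sc(test))
  }

  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    sc <- scale01(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    best <- c(acc = -1, cost = cost_grid[1], gamma = gamma_grid[1])
    for (cost in cost_grid) {
      for (gam in gamma_grid) {
        cv <- with_seed(derive_seed(seed, f),
          e1071::svm(sc$train, y[tr], kernel = "radial", cost = cost,
                     gamma = gam, cross = inner_folds, scale = FALSE))
        if (cv$tot.accuracy > best["acc"] + 1e-9) {
          best <- c(acc = cv$tot.accuracy, cost = cost, gamma = gam)
        }
      }
    }
    fit <- e1071::svm(sc$train, y[tr], kernel = "radial",
                      cost = best["cost"], gamma = best["gamma"], scale = FALSE)
    mean(predict(fit, sc$test) == y[!tr]) * 100
  }, numeric(1))

  structure(mean(acc), fold_accuracy = acc)
}

#' Exact two-sided permutation test for a difference of means
#'
#' The statistic is the difference of group means. For combined sizes up
#' to `max_exact` every \eqn{\binom{n_a+n_b}{n_a}} reassignment of the
#' pooled values is enumerated and the p-value is the fraction with
#' \eqn{|\bar{x}_a - \bar{x}_b|} at least the observed one (the observed
#' split is always included, so p > 0). Larger problems fall back to
#' Monte-Carlo with `mc_draws` random reassignments (add-one estimate).
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param max_exact Largest combined size enumerated exactly (default 20).
#' @param mc_draws Monte-Carlo draws for the fallback.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return Two-sided p-value, with attribute `"method"` (`"exact"` or
#'   `"monte-carlo"`).
#' @export
permutation_exact_test <- function(group_a, group_b, max_exact = 20,
                                   mc_draws = 10000, seed = 1) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  n <- length(pooled)
  obs <- abs(mean(group_a) - mean(group_b))
  tol <- 1e-12 * max(1, obs)
  # |mean_a - mean_b| is monotone in |sum_a - na*total/n|, so compare sums
  stat <- function(sum_a) abs(sum_a / na - (sum(pooled) - sum_a) / (n - na))
  if (n <= max_exact) {
    combos <- utils::combn(n, na)
    sums <- colSums(matrix(pooled[combos], nrow = na))
    p <- mean(vapply(sums, stat, numeric(1)) >= obs - tol)
    structure(p, method = "exact")
  } else {
    hits <- with_seed(seed, sum(vapply(seq_len(mc_draws), function(i) {
      stat(sum(pooled[sample.int(n, na)])) >= obs - tol
    }, logical(1))))
    structure((hits + 1) / (mc_draws + 1), method = "monte-carlo")
  }
}
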