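#' Mutual information between two categorical vectors
#'
#' Plug-in (maximum-likelihood) mutual information over the empirical joint
#' histogram, in bits:
#' \deqn{I(X;Y) = \sum_{a,b} p(a,b) \log_2 \frac{p(a,b)}{p(a)\,p(b)}}
#' with \eqn{0 \log 0 := 0}. No bias correction is applied; this is the
#' estimator used by the classical mRMR implementation on discretized data.
#'
#' @param x,y Vectors of equal length holding categorical values (integer
#'   codes, factors or character labels).
#' @return Mutual information in bits (non-negative, symmetric).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same length")
  if (length(x) == 0) stop("`x` and `y` must be non-empty")
  xi <- as.integer(factor(x)) - 1L
  yi <- as.integer(factor(y)) - 1L
  .mi_pair_cpp(xi, yi, max(xi) + 1L, max(yi) + 1L)
}

# Map a {-1,0,1} code matrix (features x samples) to the sample-major
# 0-based layout the C++ kernel expects.
.codes_for_cpp <- function(codes) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix (features x samples)")
  u <- sort(unique(as.vector(codes)))
  if (!all(u %in% c(-1L, 0L, 1L))) {
    stop("discrete codes must take values in {-1, 0, 1}")
  }
  m <- t(codes) + 1L
  storage.mode(m) <- "integer"
  m
}

#' Greedy mRMR feature selection under the MID criterion
#'
#' Forward selection on a discretized feature matrix. The first feature
#' maximizes the relevance \eqn{I(x; c)} with the class labels; each
#' subsequent step picks the unselected feature maximizing the mutual
#' information difference
#' \deqn{I(x_j; c) - \frac{1}{|S|} \sum_{x_i \in S} I(x_j; x_i),}
#' i.e. relevance penalized by the mean redundancy against the already
#' selected set \eqn{S}. Ties in the objective are broken by higher
#' relevance, then by lower feature index, so the ordering is deterministic.
#'
#' @param codes Integer matrix with entries in `{-1, 0, 1}` (features in
#'   rows, samples in columns), e.g. the `codes` element of [discretize()].
#' @param labels Class label per sample (length `ncol(codes)`); at least
#'   two distinct classes are required.
#' @param k Number of features to select (`1 <= k <= nrow(codes)`).
#' @return A `ranked_features` data frame with columns `feature_id`,
#'   `score` (MID objective at the step the feature was chosen) and
#'   `relevance` (\eqn{I(x; c)}), in selection order.
#' @export
mrmr_mid_select <- function(codes, labels, k) {
  m <- .codes_for_cpp(codes)
  if (length(labels) != nrow(m)) {
    stop("`labels` must have one entry per sample column of `codes`")
  }
  lab <- as.integer(factor(labels)) - 1L
  if (max(lab) < 1L) stop("feature selection needs at least two distinct class labels")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer")
  }
  if (k > ncol(m)) stop("`k` exceeds the number of features (", ncol(m), ")")
  res <- .mrmr_mid_cpp(m, lab, as.integer(k), 3L, max(lab) + 1L)
  ids <- rownames(codes)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
  out <- data.frame(feature_id = ids[res$order],
                    score = res$score,
                    relevance = res$relevance,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_features", class(out))
  out
}
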