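# Independent brute-force oracles, deliberately naive: plain loops over the
# joint histogram and a literal transcription of the MID recursion. They
# share nothing with the package's C++ path beyond the tie-break contract.

oracle_mi <- function(x, y) {
  stopifnot(length(x) == length(y))
  s <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      p <- mean(x == a & y == b)
      if (p > 0) s <- s + p * log2(p / (mean(x == a) * mean(y == b)))
    }
  }
  s
}

# Naive greedy MID selection; codes = features x samples matrix.
oracle_mid_select <- function(codes, labels, k, eps = 1e-9) {
  nf <- nrow(codes)
  rel <- vapply(seq_len(nf), function(i) oracle_mi(codes[i, ], labels),
                numeric(1))
  sel <- integer(0)
  avail <- seq_len(nf)
  while (length(sel) < k) {
    obj <- vapply(avail, function(j) {
      if (!length(sel)) rel[j]
      else rel[j] - mean(vapply(sel, function(i) {
        oracle_mi(codes[j, ], codes[i, ])
      }, numeric(1)))
    }, numeric(1))
    best <- 1
    for (t in seq_along(avail)[-1]) {
      if (obj[t] > obj[best] + eps ||
          (obj[t] > obj[best] - eps && rel[avail[t]] > rel[avail[best]] + eps)) {
        best <- t
      }
    }
    sel <- c(sel, avail[best])
    avail <- avail[-best]
  }
  rownames(codes)[sel]
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
oracle_ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  ws <- apply(combos, 2, function(i) sum(r[i]))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(sum(r[seq_len(na)]) - mu) - 1e-12)
}

# Random small abundance table for round-trip / property tests.
random_table <- function(nf = 5, ns = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(stats::runif(nf * ns, 0, 10), 6), nf, ns,
              dimnames = list(sprintf("taxon%02d", seq_len(nf)),
                              sprintf("S%02d", seq_len(ns))))
  abundance_table(m)
}

toy_metadata <- function(n, classes = 2, per_class_sub = NULL) {
  md <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                   class = rep(sprintf("class%d", seq_len(classes)),
                               each = n / classes),
                   stringsAsFactors = FALSE)
  if (!is.null(per_class_sub)) {
    md$subclass <- rep(sprintf("sub%d", seq_len(classes * per_class_sub)),
                       each = n / (classes * per_class_sub))
  }
  md
}
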