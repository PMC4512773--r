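# Ground-truth benchmark generators.
#
# All three designs share the same skeleton: 10 redundant positive marker
# groups of 10 features each (100 positives) plus 900 negative background
# features, over two classes split into subclasses. Features within a
# positive group are drawn from the same block distributions and are
# therefore mutually redundant by construction; negatives have no
# between-class difference. The designs differ in the block distributions:
# normal blocks (s1), a gamma/normal mixture (s2), and all-gamma blocks
# (s3). Gamma blocks are parameterized by shape and rate (mean = shape/rate,
# variance = shape/rate^2), the convention of R's rgamma.

# --- hard-coded block parameter tables ---------------------------------

# s2: 4 subclasses (1,2 = class 1; 3,4 = class 2) x 10 positive groups.
# Groups 1-5 are gamma in both classes; groups 6-10 are gamma in class 1
# (same parameters as groups 1-5) and normal in class 2.
.s2_gamma_shape <- rbind(
  c(7.18, 0.61, 1.70, 0.81, 2.36, 7.18, 0.61, 1.70, 0.81, 2.36),
  c(6.98, 0.51, 1.80, 0.91, 2.46, 6.98, 0.51, 1.80, 0.91, 2.46),
  c(5.70, 0.85, 1.32, 0.33, 2.88, NA, NA, NA, NA, NA),
  c(6.60, 0.75, 1.22, 0.43, 2.98, NA, NA, NA, NA, NA))
.s2_gamma_rate <- rbind(
  c(44.38, 71.12, 517, 79.70, 316, 44.38, 71.12, 517, 79.70, 316),
  c(44.38, 71.12, 517, 79.70, 316, 44.38, 71.12, 517, 79.70, 316),
  c(44.38, 27.40, 210, 91.20, 507, NA, NA, NA, NA, NA),
  c(44.38, 27.40, 210, 91.20, 507, NA, NA, NA, NA, NA))
.s2_norm_mean <- rbind(
  c(NA, NA, NA, NA, NA, 0.14, 0.009, 0.005, 0.004, 0.009),
  c(NA, NA, NA, NA, NA, 0.13, 0.010, 0.004, 0.003, 0.010))
# group 10's class-2 sd follows the design rule for groups 6-10 (moments of
# the matching class-2 gamma block, here gamma(2.88, 507): sd ~ 0.003)
.s2_norm_sd <- rbind(
  c(NA, NA, NA, NA, NA, 0.06, 0.007, 0.002, 0.006, 0.003),
  c(NA, NA, NA, NA, NA, 0.06, 0.007, 0.002, 0.006, 0.003))
.s2_neg_mean <- 0.14
.s2_neg_sd <- 0.06

# s3: 6 subclasses (1-3 = class 1; 4-6 = class 2) x 10 positive groups,
# all gamma; plus 3 negative groups of 300 features, subclass-invariant.
.s3_shape <- rbind(
  c(7.18, 0.61, 2.22, 1.70, 1.29, 0.87, 0.81, 2.56, 1.50, 1.66),
  c(7.38, 0.71, 2.12, 1.80, 1.19, 0.67, 0.91, 2.46, 1.50, 1.56),
  c(6.98, 0.51, 2.02, 1.90, 1.09, 0.77, 1.01, 2.36, 1.50, 1.46),
  c(5.70, 0.85, 1.72, 0.92, 0.50, 1.37, 0.53, 3.28, 0.91, 2.49),
  c(5.60, 0.75, 1.62, 0.82, 0.40, 1.47, 0.43, 3.28, 0.81, 2.39),
  c(5.80, 0.95, 1.52, 0.72, 0.60, 1.57, 0.33, 3.28, 0.71, 2.59))
.s3_rate <- rbind(
  c(44.38, 71.12, 33.40, 517, 94.70, 203, 79.70, 316, 44.4, 66.16),
  c(44.38, 71.12, 33.40, 517, 94.70, 203, 79.70, 316, 44.4, 66.16),
  c(44.38, 71.12, 33.40, 517, 94.70, 203, 79.70, 316, 44.4, 66.16),
  c(44.38, 27.40, 37.68, 210, 66.20, 734, 91.20, 507, 42.32, 171),
  c(44.38, 27.40, 37.68, 210, 66.20, 734, 91.20, 507, 42.32, 171),
  c(44.38, 27.40, 37.68, 210, 66.20, 734, 91.20, 507, 42.32, 171))
.s3_neg_shape <- c(6.20, 3.10, 0.61)
.s3_neg_rate <- c(24.30, 66.40, 71.10)

.pos_ids <- function() {
  as.vector(vapply(1:10, function(g) sprintf("pos_g%02d_f%02d", g, 1:10),
                   character(10)))
}

.make_metadata <- function(n_sub, per_sub) {
  n <- n_sub * per_sub
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             class = rep(c("class1", "class2"), each = n / 2),
             subclass = rep(sprintf("subclass%d", seq_len(n_sub)),
                            each = per_sub),
             stringsAsFactors = FALSE)
}

.make_truth <- function(neg_groups = 1) {
  per <- 900 / neg_groups
  data.frame(
    feature_id = c(.pos_ids(),
                   as.vector(vapply(seq_len(neg_groups), function(g) {
                     sprintf("neg_g%d_f%03d", g, seq_len(per))
                   }, character(per)))),
    group_id = c(rep(sprintf("pos%02d", 1:10), each = 10),
                 rep(sprintf("neg%d", seq_len(neg_groups)), each = per)),
    is_positive = rep(c(TRUE, FALSE), c(100, 900)),
    stringsAsFactors = FALSE)
}

.as_synthetic <- function(values, metadata, truth, provenance) {
  rownames(values) <- truth$feature_id
  colnames(values) <- metadata$sample_id
  structure(list(table = abundance_table(values, prenormalized = TRUE),
                 metadata = metadata, truth = truth,
                 provenance = provenance),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset '%s': %d features x %d samples, %d positive / %d negative\n",
              x$provenance$design, nrow(x$table$values), ncol(x$table$values),
              sum(x$truth$is_positive), sum(!x$truth$is_positive)))
  invisible(x)
}

#' Normal-block benchmark dataset (s1)
#'
#' 1,000 features x 120 samples: 2 classes x 3 subclasses x 20 samples.
#' Every (feature, subclass) block of 20 samples is normal with a common
#' `sd`. For positive groups 1-5 the block mean is drawn uniformly from
#' {11, 12, 13, 14} in the class-1 subclasses (1-3) and from
#' {17, 18, 19, 20} in the class-2 subclasses (4-6); groups 6-10 use the
#' two mean vectors the other way round. The 900 negatives all have mean
#' 15. Block means are redrawn independently per feature and per subclass
#' and recorded in the provenance (`drawn_means`).
#'
#' @param sd Common standard deviation of every feature (> 0); controls
#'   the difficulty of the design.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param means_per_feature Draw one mean per feature shared across the
#'   three subclasses of a class, instead of the default independent draw
#'   per (feature, subclass).
#' @return A `synthetic_dataset`: `table` (pre-normalized
#'   `abundance_table`), `metadata`, `truth` (`feature_id`, `group_id`,
#'   `is_positive`) and `provenance`.
#' @export
generate_s1 <- function(sd = 1, seed = 1, means_per_feature = FALSE) {
  if (!is.numeric(sd) || length(sd) != 1 || sd <= 0) stop("`sd` must be > 0")
  metadata <- .make_metadata(6, 20)
  truth <- .make_truth(1)
  low <- c(11, 12, 13, 14)
  high <- c(17, 18, 19, 20)
  with_seed(seed, {
    pos <- matrix(0, 100, 120)
    drawn <- matrix(NA_real_, 100, 6,
                    dimnames = list(.pos_ids(), sprintf("subclass%d", 1:6)))
    for (g in 1:10) {
      for (j in 1:10) {
        f <- (g - 1) * 10 + j
        if (means_per_feature) {
          m1 <- sample(if (g <= 5) low else high, 1)
          m2 <- sample(if (g <= 5) high else low, 1)
          mus <- c(m1, m1, m1, m2, m2, m2)
        } else {
          mus <- c(sample(if (g <= 5) low else high, 3, replace = TRUE),
                   sample(if (g <= 5) high else low, 3, replace = TRUE))
        }
        drawn[f, ] <- mus
        for (s in 1:6) {
          pos[f, ((s - 1) * 20 + 1):(s * 20)] <- stats::rnorm(20, mus[s], sd)
        }
      }
    }
    neg <- matrix(stats::rnorm(900 * 120, mean = 15, sd = sd), nrow = 900)
    .as_synthetic(rbind(pos, neg), metadata, truth,
                  list(design = "s1", sd = sd, seed = seed,
                       means_per_feature = means_per_feature,
                       drawn_means = drawn))
  })
}

#' Gamma/normal mixture benchmark dataset (s2)
#'
#' 1,000 features x 100 samples: 2 classes x 2 subclasses x 25 samples.
#' Positive groups 1-5 are gamma-distributed in both classes and differ
#' between classes mainly in shape; groups 6-10 are gamma in class 1 (same
#' parameters as groups 1-5) but normal in class 2, mimicking taxa whose
#' distribution family itself changes with phenotype. The 900 negatives
#' are normal(0.14, 0.06) in every subclass. All block parameters are
#' fixed constants of the design and echoed in the provenance.
#'
#' @inheritParams generate_s1
#' @return A `synthetic_dataset`; see [generate_s1()].
#' @export
generate_s2 <- function(seed = 1) {
  metadata <- .make_metadata(4, 25)
  truth <- .make_truth(1)
  with_seed(seed, {
    pos <- matrix(0, 100, 100)
    for (g in 1:10) {
      for (j in 1:10) {
        f <- (g - 1) * 10 + j
        for (s in 1:4) {
          cols <- ((s - 1) * 25 + 1):(s * 25)
          sh <- .s2_gamma_shape[s, g]
          pos[f, cols] <- if (!is.na(sh)) {
            stats::rgamma(25, shape = sh, rate = .s2_gamma_rate[s, g])
          } else {
            stats::rnorm(25, .s2_norm_mean[s - 2, g], .s2_norm_sd[s - 2, g])
          }
        }
      }
    }
    neg <- matrix(stats::rnorm(900 * 100, .s2_neg_mean, .s2_neg_sd), nrow = 900)
    .as_synthetic(rbind(pos, neg), metadata, truth,
                  list(design = "s2", seed = seed,
                       gamma_shape = .s2_gamma_shape, gamma_rate = .s2_gamma_rate,
                       normal_mean = .s2_norm_mean, normal_sd = .s2_norm_sd,
                       negative = c(mean = .s2_neg_mean, sd = .s2_neg_sd)))
  })
}

#' All-gamma benchmark dataset (s3)
#'
#' 1,000 features x 120 samples: 2 classes x 3 subclasses x 20 samples
#' (60 per class). All blocks are gamma-distributed; positive groups
#' differ between classes in shape (and rate), while the three negative
#' groups of 300 features each use the same subclass-invariant parameters
#' everywhere. Block parameters are fixed constants of the design and
#' echoed in the provenance.
#'
#' @inheritParams generate_s1
#' @return A `synthetic_dataset`; see [generate_s1()].
#' @export
generate_s3 <- function(seed = 1) {
  metadata <- .make_metadata(6, 20)
  truth <- .make_truth(3)
  with_seed(seed, {
    pos <- matrix(0, 100, 120)
    for (g in 1:10) {
      for (j in 1:10) {
        f <- (g - 1) * 10 + j
        for (s in 1:6) {
          cols <- ((s - 1) * 20 + 1):(s * 20)
          pos[f, cols] <- stats::rgamma(20, shape = .s3_shape[s, g],
                                        rate = .s3_rate[s, g])
        }
      }
    }
    neg <- matrix(0, 900, 120)
    for (g in 1:3) {
      rows <- ((g - 1) * 300 + 1):(g * 300)
      neg[rows, ] <- matrix(
        stats::rgamma(300 * 120, shape = .s3_neg_shape[g],
                      rate = .s3_neg_rate[g]), nrow = 300)
    }
    .as_synthetic(rbind(pos, neg), metadata, truth,
                  list(design = "s3", seed = seed,
                       shape = .s3_shape, rate = .s3_rate,
                       negative_shape = .s3_neg_shape,
                       negative_rate = .s3_neg_rate))
  })
}

#' Generate a benchmark dataset by design name
#'
#' @param design One of `"s1"`, `"s2"`, `"s3"`.
#' @param sd Standard deviation for the s1 design (ignored otherwise).
#' @param seed Integer seed.
#' @return A `synthetic_dataset`.
#' @export
generate_benchmark <- function(design = c("s1", "s2", "s3"), sd = 1, seed = 1) {
  design <- match.arg(design)
  switch(design,
         s1 = generate_s1(sd = sd, seed = seed),
         s2 = generate_s2(seed = seed),
         s3 = generate_s3(seed = seed))
}

#' Write the ground truth of a synthetic dataset to TSV
#'
#' @param truth A truth data frame (`feature_id`, `group_id`,
#'   `is_positive`) or a `synthetic_dataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  if (inherits(truth, "synthetic_dataset")) truth <- truth$truth
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$is_positive <- as.logical(df$is_positive)
  df
}
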