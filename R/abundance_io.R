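#' Construct an abundance table
#'
#' An `abundance_table` holds a feature-by-sample numeric matrix (taxa as
#' rows, samples as columns — the orientation of mothur/QIIME summary
#' exports) together with a flag recording whether each sample column has
#' been normalized to sum to one.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names are taken as feature ids, column names as sample ids; both
#'   must be present and unique.
#' @param normalized Logical; `TRUE` declares the columns to be relative
#'   abundances summing to one (checked when `TRUE`).
#' @param prenormalized Logical; `TRUE` marks data that should be used as-is
#'   (no further normalization before discretization) even though columns do
#'   not sum to one. The synthetic benchmark generators set this because
#'   their distributions are defined on the raw generated values.
#'
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (the matrix), `is_normalized` and `prenormalized`.
#' @export
abundance_table <- function(values, normalized = FALSE, prenormalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must carry feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(fid)) stop("duplicate feature ids: ",
                               paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid)) stop("duplicate sample ids: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values)) stop("`values` contains missing entries")
  if (isTRUE(normalized)) {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9)) {
      stop("normalized = TRUE but some sample columns do not sum to 1")
    }
  }
  structure(list(values = values, is_normalized = isTRUE(normalized),
                 prenormalized = isTRUE(prenormalized)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_normalized) "relative abundances" else "raw values"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Feature and sample identifiers of an abundance table
#' @param table An `abundance_table`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(table) rownames(table$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(table) colnames(table$values)

#' Validate a sample metadata table
#'
#' Sample metadata maps each sample id to a class label and, optionally, a
#' subclass label. Classes are what biomarkers must discriminate; subclasses
#' define the strata preserved by the bootstrap.
#'
#' @param metadata A data frame with columns `sample_id`, `class` and
#'   optionally `subclass`.
#' @param table Optional `abundance_table` the metadata must pair with; when
#'   given, every table sample must have exactly one metadata record and the
#'   records are reordered to the table's column order.
#' @return The validated (and possibly reordered) metadata data frame.
#' @export
sample_metadata <- function(metadata, table = NULL) {
  if (!is.data.frame(metadata)) stop("`metadata` must be a data frame")
  need <- c("sample_id", "class")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks required column(s): ",
                         paste(miss, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$class <- as.character(metadata$class)
  if (!is.null(metadata$subclass)) metadata$subclass <- as.character(metadata$subclass)
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata has duplicate sample_id record(s)")
  }
  if (!is.null(table)) {
    sid <- sample_ids(table)
    extra <- setdiff(metadata$sample_id, sid)
    if (length(extra)) {
      stop("metadata sample(s) absent from abundance table: ",
           paste(extra, collapse = ", "))
    }
    absent <- setdiff(sid, metadata$sample_id)
    if (length(absent)) {
      stop("table sample(s) without metadata record: ",
           paste(absent, collapse = ", "))
    }
    metadata <- metadata[match(sid, metadata$sample_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  metadata
}

#' Read an abundance table and its sample metadata
#'
#' Both files are UTF-8 TSV. The abundance table has feature ids in the
#' first column (header cell `feature_id`) and one column per sample; the
#' metadata file has columns `sample_id`, `class` and optionally `subclass`.
#'
#' @param path Path to the abundance TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param transpose Set `TRUE` when the file stores samples in rows and
#'   features in columns.
#' @return A list with elements `table` (`abundance_table`) and `metadata`
#'   (data frame aligned to the table's sample order).
#' @export
read_abundance_table <- function(path, metadata_path, transpose = FALSE) {
  for (p in c(path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  if (ncol(raw) < 2) stop("abundance table needs an id column plus >= 1 sample")
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop(sprintf("non-numeric value in column '%s'%s",
                   names(vals)[j],
                   if (length(bad)) paste0(", row '", ids[bad[1]], "'") else ""))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyNA(m)) stop("abundance table contains missing values")
  md <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  tab <- abundance_table(m)
  md <- sample_metadata(md, tab)
  list(table = tab, metadata = md)
}

#' Write an abundance table / metadata / ground truth to TSV
#'
#' Inverse of [read_abundance_table()]; values are written in full double
#' precision so a round trip reproduces the table.
#'
#' @param table An `abundance_table`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(feature_id = feature_ids(table),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @param metadata A sample metadata data frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-sample normalization to relative abundances
#'
#' Divides every sample column by its total so each column sums to one —
#' the standard conversion of read counts into relative abundances.
#' Idempotent: normalizing an already-normalized table is a no-op.
#'
#' @param table An `abundance_table` with non-negative values.
#' @return The normalized `abundance_table` (`is_normalized = TRUE`).
#' @export
normalize_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (any(v < 0)) stop("negative values cannot be normalized to relative abundances")
  cs <- colSums(v)
  if (any(cs == 0)) {
    stop("degenerate sample(s) with zero total abundance: ",
         paste(colnames(v)[cs == 0], collapse = ", "))
  }
  abundance_table(sweep(v, 2, cs, "/"), normalized = TRUE)
}

#' Remove features that are almost always absent
#'
#' Drops every feature whose fraction of exactly-zero entries is at least
#' `zero_fraction` (default: features that are zero in 80% or more of the
#' samples). Rare, mostly-absent taxa carry little signal and destabilize
#' discretization.
#'
#' @param table An `abundance_table`.
#' @param zero_fraction Removal threshold in (0, 1]; a feature is removed
#'   when its zero fraction is `>=` this value (the boundary is removed).
#' @return The filtered `abundance_table`, with the removed feature ids in
#'   attribute `"removed_features"`.
#' @export
filter_sparse <- function(table, zero_fraction = 0.8) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(zero_fraction) || length(zero_fraction) != 1 ||
      zero_fraction <= 0 || zero_fraction > 1) {
    stop("`zero_fraction` must be a single value in (0, 1]")
  }
  zf <- rowMeans(table$values == 0)
  drop <- zf >= zero_fraction
  if (all(drop)) stop("all features removed by the sparsity filter")
  kept <- table$values[!drop, , drop = FALSE]
  # dropping features from a normalized table leaves columns summing to
  # slightly below one; the surviving values are still the abundances to
  # use, so the table is carried forward as-is rather than rescaled
  out <- abundance_table(kept,
                         normalized = table$is_normalized && !any(drop),
                         prenormalized = table$prenormalized ||
                           (table$is_normalized && any(drop)))
  attr(out, "removed_features") <- feature_ids(table)[drop]
  out
}

#' Three-level discretization around the feature mean
#'
#' Each feature is coded against its own mean \eqn{\mu} and standard
#' deviation \eqn{\sigma} across samples: values above
#' \eqn{\mu + \sigma/2} become +1, values below \eqn{\mu - \sigma/2} become
#' -1, everything else 0 (boundaries map to 0; the inequalities are strict).
#' Collapsing abundances to {-1, 0, +1} suppresses measurement noise and
#' makes the mutual-information machinery applicable. Constant features
#' (\eqn{\sigma = 0}) code to all zeros.
#'
#' @param table An `abundance_table`; must be normalized (or flagged as
#'   pre-normalized, as the synthetic generators do) with at least two
#'   samples.
#' @param sd_denominator `"n-1"` (default, sample standard deviation) or
#'   `"n"` (population form).
#' @return A list with `codes` (integer matrix in {-1, 0, 1}, same
#'   dimnames as the table) and `model` (data frame `feature_id`, `mu`,
#'   `sigma`).
#' @export
discretize <- function(table, sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(table, "abundance_table"))
  sd_denominator <- match.arg(sd_denominator)
  if (!table$is_normalized && !isTRUE(table$prenormalized)) {
    stop("table is not normalized; run normalize_relative() first ",
         "(or construct with prenormalized = TRUE for data to be used as-is)")
  }
  v <- table$values
  n <- ncol(v)
  if (n < 2) stop("discretization needs at least two samples")
  mu <- rowMeans(v)
  sigma <- sqrt(rowSums((v - mu)^2) /
                  (if (sd_denominator == "n-1") n - 1 else n))
  hi <- mu + sigma / 2
  lo <- mu - sigma / 2
  codes <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  codes[v > hi] <- 1L
  codes[v < lo] <- -1L
  list(codes = codes,
       model = data.frame(feature_id = rownames(v), mu = mu, sigma = sigma,
                          row.names = NULL, stringsAsFactors = FALSE))
}
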