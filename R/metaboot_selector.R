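#' Parameters of the bootstrap biomarker selector
#'
#' @param M First-stage candidate count: the size of the initial mRMR
#'   screen on the full data. Must exceed `M_prime`.
#' @param B Number of stratified bootstrap replicates.
#' @param M_prime Final biomarker count, also the per-bootstrap selection
#'   size.
#' @param seed Integer root seed; every random draw of the selector derives
#'   from it.
#' @return A `metaboot_params` list.
#' @export
metaboot_params <- function(M = 50, B = 40, M_prime = 10, seed = 1) {
  for (v in list(M = M, B = B, M_prime = M_prime)) {
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      stop("M, B and M_prime must be positive integers")
    }
  }
  if (M <= M_prime) stop("M must be greater than M_prime")
  structure(list(M = as.integer(M), B = as.integer(B),
                 M_prime = as.integer(M_prime), seed = as.integer(seed)),
            class = "metaboot_params")
}

# Deterministic child-seed stream: bootstrap b of root seed s gets its own
# seed without consuming the global RNG, so growing B never reshuffles
# earlier replicates.
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 30269
  s <- s %% 2147483647
  as.integer(if (s == 0) 1 else s)
}

# Evaluate expr with a local RNG seeded at `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stratified bootstrap preserving the sample-group structure
#'
#' Draws, independently within each stratum, as many samples with
#' replacement as the stratum originally contains, so the resampled dataset
#' has exactly the original per-stratum composition ("the same structure"):
#' only the multiplicity of individual samples changes. Strata are the
#' subclasses when the metadata has them, otherwise the classes.
#'
#' @param metadata Sample metadata data frame (columns `sample_id`,
#'   `class`, optional `subclass`). Row order defines the sample indices.
#' @return Integer vector of sampled indices (with repetition), grouped by
#'   stratum in order of first appearance. Uses the current RNG state; seed
#'   beforehand for reproducibility.
#' @export
stratified_bootstrap <- function(metadata) {
  metadata <- sample_metadata(metadata)
  strat <- if (!is.null(metadata$subclass)) metadata$subclass else metadata$class
  if (anyNA(strat) || any(!nzchar(strat))) stop("empty stratum label")
  out <- integer(0)
  for (s in unique(strat)) {
    idx <- which(strat == s)
    out <- c(out, idx[sample.int(length(idx), length(idx), replace = TRUE)])
  }
  out
}

#' Bootstrap-stabilized mRMR biomarker selection
#'
#' The full selector: (1) one mRMR/MID screen on the discretized table
#' keeps the `M` most promising candidates; (2) `B` stratified bootstrap
#' replicates each re-select `M_prime` features from those candidates by
#' mRMR on the resampled columns; (3) candidates are ranked by how many of
#' the `B` bootstrap lists they appear in, and the `M_prime` most frequent
#' become the final biomarkers. The bootstrap stage eliminates features
#' whose selection depends on particular samples — negatives and unstable
#' redundant positives — leaving markers that are discriminative *and*
#' reproducible under resampling.
#'
#' Discretization codes are computed once on the full table and reused in
#' every bootstrap replicate (set `rediscretize = TRUE` to re-estimate the
#' per-feature thresholds within each replicate instead). Bootstrap
#' replicates where a class collapses to few distinct samples are kept as
#' drawn: relevance may then vanish and selection falls back to the
#' deterministic tie-break order.
#'
#' @param table Normalized (or pre-normalized) `abundance_table`, already
#'   sparsity-filtered.
#' @param metadata Paired sample metadata; classes drive relevance,
#'   subclasses (when present) define bootstrap strata.
#' @param params A [metaboot_params()] object.
#' @param rediscretize Re-run [discretize()] inside each bootstrap
#'   replicate (default `FALSE`).
#' @return A `biomarker_result` list: `features` (final `M_prime` ids in
#'   rank order), `candidates` (data frame over all `M` first-stage
#'   candidates with `feature_id`, `first_stage_rank`, `occurrence`,
#'   `mean_bootstrap_rank`), `selections` (per-bootstrap ordered id lists),
#'   `bootstrap_indices`, `params`.
#' @export
run_metaboot <- function(table, metadata, params = metaboot_params(),
                         rediscretize = FALSE) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(params, "metaboot_params"))
  metadata <- sample_metadata(metadata, table)
  if (length(unique(metadata$class)) < 2) {
    stop("biomarker selection needs at least two classes")
  }
  if (params$M > nrow(table$values)) {
    stop("M exceeds the number of features after filtering")
  }
  codes <- discretize(table)$codes
  first <- mrmr_mid_select(codes, metadata$class, params$M)
  cand <- first$feature_id
  cand_codes <- codes[cand, , drop = FALSE]

  selections <- vector("list", params$B)
  indices <- vector("list", params$B)
  for (b in seq_len(params$B)) {
    idx <- with_seed(derive_seed(params$seed, b), stratified_bootstrap(metadata))
    indices[[b]] <- idx
    bc <- if (rediscretize) {
      bt <- abundance_table(
        `colnames<-`(table$values[, idx, drop = FALSE],
                     sprintf("bs%d", seq_along(idx))),
        prenormalized = TRUE) # columns are resampled originals
      discretize(bt)$codes[cand, , drop = FALSE]
    } else {
      cand_codes[, idx, drop = FALSE]
    }
    selections[[b]] <- mrmr_mid_select(bc, metadata$class[idx],
                                       params$M_prime)$feature_id
  }

  ranked <- rank_by_occurrence(selections, params$M_prime, candidates = cand)
  structure(list(features = ranked$feature_id[seq_len(params$M_prime)],
                 candidates = ranked,
                 selections = selections,
                 bootstrap_indices = indices,
                 params = params),
            class = "biomarker_result")
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat(sprintf("biomarker_result: %d biomarkers from %d candidates (B = %d, seed = %d)\n",
              length(x$features), nrow(x$candidates), x$params$B, x$params$seed))
  print(utils::head(x$candidates, length(x$features)))
  invisible(x)
}

#' Rank candidate features by bootstrap occurrence
#'
#' Counts, for every candidate, the number of bootstrap selection lists it
#' appears in and orders candidates by descending count. Ties are broken by
#' lower mean within-bootstrap rank (features consistently chosen early win),
#' then by lower first-stage rank.
#'
#' @param selections List of ordered feature-id vectors, one per bootstrap,
#'   each of length `M_prime`.
#' @param M_prime Per-bootstrap selection size (consistency-checked).
#' @param candidates Ordered first-stage candidate ids (defines the
#'   first-stage rank used for tie-breaking and guarantees zero-count
#'   candidates appear). Defaults to the union of the selections.
#' @return Data frame `feature_id`, `first_stage_rank`, `occurrence`,
#'   `mean_bootstrap_rank`, ordered by the ranking.
#' @export
rank_by_occurrence <- function(selections, M_prime, candidates = NULL) {
  if (!length(selections)) stop("empty selection list")
  lens <- lengths(selections)
  if (any(lens != M_prime)) stop("every bootstrap selection must have length M_prime")
  if (is.null(candidates)) candidates <- unique(unlist(selections))
  if (!all(unlist(selections) %in% candidates)) {
    stop("bootstrap selections contain features outside the candidate set")
  }
  occ <- integer(length(candidates))
  ranksum <- numeric(length(candidates))
  names(occ) <- names(ranksum) <- candidates
  for (sel in selections) {
    occ[sel] <- occ[sel] + 1L
    ranksum[sel] <- ranksum[sel] + seq_along(sel)
  }
  meanrank <- ifelse(occ > 0, ranksum / occ, Inf)
  ord <- order(-occ, meanrank, seq_along(candidates))
  data.frame(feature_id = candidates[ord],
             first_stage_rank = seq_along(candidates)[ord],
             occurrence = occ[ord],
             mean_bootstrap_rank = meanrank[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Saturation sweep over the candidate count M and bootstrap count B
#'
#' Supports the elbow procedure for choosing the selector's parameters:
#' for each `M` on the grid, how many distinct marker groups (or distinct
#' features, when no ground truth is supplied) the first-stage top-`M`
#' screen captures; for each `B`, how many distinct features appear in any
#' of the first `B` bootstrap top-`M_prime` lists. Bootstrap streams are
#' nested (replicate `b` is identical for every grid point), so the
#' B-curve is non-decreasing and the sweep costs one pass at `max(B_grid)`.
#'
#' @param table,metadata,params As in [run_metaboot()].
#' @param M_grid,B_grid Integer grids to sweep.
#' @param truth Optional ground-truth data frame (`feature_id`,
#'   `group_id`); when given, the M-sweep counts distinct positive groups.
#' @return List of data frames `M_sweep` (`M`, `unique_count`) and
#'   `B_sweep` (`B`, `unique_count`).
#' @export
sweep_parameters <- function(table, metadata, M_grid, B_grid,
                             params = metaboot_params(), truth = NULL) {
  if (!length(M_grid) || !length(B_grid)) stop("grids must be non-empty")
  metadata <- sample_metadata(metadata, table)
  codes <- discretize(table)$codes

  count_units <- function(ids) {
    if (is.null(truth)) return(length(unique(ids)))
    g <- truth$group_id[match(ids, truth$feature_id)]
    pos <- if (!is.null(truth$is_positive)) {
      truth$is_positive[match(ids, truth$feature_id)]
    } else rep(TRUE, length(ids))
    length(unique(g[pos]))
  }

  kmax <- min(max(M_grid), nrow(codes))
  full <- mrmr_mid_select(codes, metadata$class, kmax)$feature_id
  m_sweep <- data.frame(
    M = M_grid,
    unique_count = vapply(M_grid, function(m) {
      count_units(full[seq_len(min(m, kmax))])
    }, numeric(1)))

  run <- run_metaboot(table, metadata,
                      metaboot_params(M = params$M, B = max(B_grid),
                                      M_prime = params$M_prime,
                                      seed = params$seed))
  b_sweep <- data.frame(
    B = B_grid,
    unique_count = vapply(B_grid, function(b) {
      length(unique(unlist(run$selections[seq_len(b)])))
    }, numeric(1)))

  list(M_sweep = m_sweep, B_sweep = b_sweep)
}

#' Write a biomarker result to TSV with a JSON provenance sidecar
#'
#' @param result A `biomarker_result`.
#' @param path Output TSV path (candidate table with occurrence ranks); a
#'   `<path>.json` sidecar records the parameters and seed.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(result, path) {
  stopifnot(inherits(result, "biomarker_result"))
  tab <- result$candidates
  tab$final <- tab$feature_id %in% result$features
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(M = result$params$M, B = result$params$B,
         M_prime = result$params$M_prime, seed = result$params$seed,
         features = result$features),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
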