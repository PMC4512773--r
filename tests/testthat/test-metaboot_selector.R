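test_that("metaboot_params validates its fields", {
  p <- metaboot_params()
  expect_identical(c(p$M, p$B, p$M_prime), c(50L, 40L, 10L))
  expect_error(metaboot_params(M = 10, M_prime = 10), "greater")
  expect_error(metaboot_params(M = 0), "positive")
})

test_that("stratified bootstrap preserves stratum composition and is seed-deterministic", {
  md <- toy_metadata(20, classes = 2, per_class_sub = 2) # 4 strata of 5
  set.seed(1)
  idx <- stratified_bootstrap(md)
  expect_length(idx, 20)
  for (s in unique(md$subclass)) {
    members <- which(md$subclass == s)
    expect_length(idx[idx %in% members], length(members))
  }
  # single stratum: plain resampling of all indices
  md1 <- toy_metadata(5, classes = 1)
  set.seed(2)
  i1 <- stratified_bootstrap(md1)
  expect_true(all(i1 %in% 1:5) && length(i1) == 5)

  # class used as stratum when no subclass; 2 + 3 split conserved
  md2 <- data.frame(sample_id = paste0("S", 1:5),
                    class = c("A", "A", "B", "B", "B"))
  set.seed(3)
  i2 <- stratified_bootstrap(md2)
  expect_length(i2[i2 %in% 1:2], 2)
  expect_length(i2[i2 %in% 3:5], 3)

  set.seed(99); a <- stratified_bootstrap(md)
  set.seed(99); b <- stratified_bootstrap(md)
  expect_identical(a, b)
  set.seed(100); c1 <- stratified_bootstrap(md)
  expect_false(identical(a, c1))
})

test_that("rank_by_occurrence counts and tie-breaks as specified", {
  sels <- list(c("a", "b", "c"), c("a", "c", "d"), c("a", "d", "b"))
  r <- rank_by_occurrence(sels, 3, candidates = c("a", "b", "c", "d", "e"))
  expect_identical(r$feature_id[1], "a")
  expect_identical(r$occurrence[1], 3L)
  expect_true(all(r$occurrence <= 3 & r$occurrence >= 0))
  expect_identical(r$feature_id[5], "e")
  expect_identical(r$occurrence[5], 0L)
  # b, c, d all occur twice; mean ranks: b (2+3)/2=2.5, c (3+2)/2=2.5, d (3+2)/2=2.5
  # -> falls to first-stage rank: b before c before d
  expect_identical(r$feature_id[2:4], c("b", "c", "d"))

  # mean-rank tie-break: same counts, one always first, one always last
  sels2 <- list(c("x", "q", "y"), c("x", "q", "y"))
  r2 <- rank_by_occurrence(sels2, 3, candidates = c("y", "x", "q"))
  expect_identical(r2$feature_id[1], "x") # count tie, mean rank 1 vs 3
  expect_error(rank_by_occurrence(list(), 3), "empty")
  expect_error(rank_by_occurrence(list(c("a", "b")), 3), "length")
})

test_that("run_metaboot recovers informative features and is reproducible", {
  # 3 features tracking the class plus 7 noise features
  set.seed(5)
  n <- 40
  cls <- rep(c("c1", "c2"), each = n / 2)
  m <- rbind(matrix(rep(ifelse(cls == "c1", 0, 1), 3), 3, n, byrow = TRUE) +
               matrix(rnorm(3 * n, sd = 0.01), 3, n),
             matrix(rnorm(7 * n), 7, n))
  dimnames(m) <- list(c(paste0("info", 1:3), paste0("noise", 1:7)),
                      paste0("S", 1:n))
  tab <- abundance_table(m, prenormalized = TRUE)
  md <- data.frame(sample_id = colnames(m), class = cls)
  res <- run_metaboot(tab, md, metaboot_params(M = 5, B = 10, M_prime = 3, seed = 42))
  expect_setequal(res$features, paste0("info", 1:3))

  # bit-identical rerun under the same seed
  res2 <- run_metaboot(tab, md, metaboot_params(M = 5, B = 10, M_prime = 3, seed = 42))
  expect_identical(res$features, res2$features)
  expect_identical(res$candidates, res2$candidates)
  expect_identical(res$bootstrap_indices, res2$bootstrap_indices)

  # occurrence counts over candidates always total B * M_prime
  expect_identical(sum(res$candidates$occurrence), 10L * 3L)
  # final biomarkers are candidates; candidates are table features
  expect_true(all(res$features %in% res$candidates$feature_id))
  expect_true(all(res$candidates$feature_id %in% feature_ids(tab)))
  expect_length(res$features, 3)

  # every bootstrap conserves per-stratum sample counts
  md$subclass <- rep(c("a", "b", "c", "d"), each = n / 4)
  res3 <- run_metaboot(tab, md, metaboot_params(M = 5, B = 8, M_prime = 3, seed = 7))
  strat <- md$subclass
  for (idx in res3$bootstrap_indices) {
    expect_identical(as.vector(table(strat[idx])), as.vector(table(strat)))
  }

  # B = 1 equals the top-M' of that single bootstrapped selection
  res1 <- run_metaboot(tab, md, metaboot_params(M = 5, B = 1, M_prime = 3, seed = 9))
  expect_setequal(res1$features, res1$selections[[1]])

  expect_error(run_metaboot(tab, md, metaboot_params(M = 50, B = 2, M_prime = 10)),
               "exceeds")
  md_one <- md; md_one$class <- "c1"
  expect_error(run_metaboot(tab, md_one, metaboot_params(M = 5, B = 2, M_prime = 3)),
               "two classes")
})

test_that("bootstrap child streams are nested: growing B never changes earlier replicates", {
  set.seed(3)
  n <- 24
  cls <- rep(c("c1", "c2"), each = n / 2)
  m <- matrix(rnorm(8 * n), 8, n,
              dimnames = list(paste0("f", 1:8), paste0("S", 1:n)))
  m[1, ] <- m[1, ] + ifelse(cls == "c1", 0, 3)
  tab <- abundance_table(m, prenormalized = TRUE)
  md <- data.frame(sample_id = colnames(m), class = cls)
  small <- run_metaboot(tab, md, metaboot_params(M = 4, B = 5, M_prime = 2, seed = 13))
  big <- run_metaboot(tab, md, metaboot_params(M = 4, B = 12, M_prime = 2, seed = 13))
  expect_identical(big$selections[1:5], small$selections)
  expect_identical(big$bootstrap_indices[1:5], small$bootstrap_indices)
})

test_that("sweep_parameters reports saturation counts with a monotone B-curve", {
  d <- generate_s1(sd = 1, seed = 21)
  sw <- sweep_parameters(d$table, d$metadata, M_grid = c(10, 30, 50),
                         B_grid = c(5, 10, 20), params = metaboot_params(seed = 21),
                         truth = d$truth)
  expect_identical(names(sw), c("M_sweep", "B_sweep"))
  expect_true(all(diff(sw$B_sweep$unique_count) >= 0)) # nested streams
  expect_true(all(sw$M_sweep$unique_count <= 10)) # at most 10 positive groups

  # without truth, an exhaustive M equals the distinct feature count
  codes_small <- d$table$values[1:30, , drop = FALSE]
  tab_small <- abundance_table(codes_small, prenormalized = TRUE)
  sw2 <- sweep_parameters(tab_small, d$metadata, M_grid = 30, B_grid = 2,
                          params = metaboot_params(M = 20, B = 2, M_prime = 5, seed = 3))
  expect_identical(sw2$M_sweep$unique_count, 30)
})

test_that("biomarker results round-trip through the TSV + JSON writer", {
  set.seed(8)
  n <- 20
  m <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(paste0("f", 1:6), paste0("S", 1:n)))
  cls <- rep(c("x", "y"), each = n / 2)
  m[2, ] <- m[2, ] + ifelse(cls == "x", 0, 2)
  tab <- abundance_table(m, prenormalized = TRUE)
  md <- data.frame(sample_id = colnames(m), class = cls)
  res <- run_metaboot(tab, md, metaboot_params(M = 4, B = 3, M_prime = 2, seed = 2))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_biomarkers(res, tf)
  back <- utils::read.delim(tf)
  expect_identical(back$feature_id, res$candidates$feature_id)
  side <- jsonlite::read_json(paste0(tf, ".json"), simplifyVector = TRUE)
  expect_identical(side$seed, 2L)
  expect_identical(side$features, res$features)
})

test_that("at small dispersion every final biomarker on the normal benchmark is a positive marker", {
  for (s in 1:5) {
    d <- generate_s1(sd = 0.5, seed = 400 + s)
    res <- run_metaboot(d$table, d$metadata, metaboot_params(seed = s))
    sc <- score_selection(res$features, d$truth)
    expect_identical(sc$positive_count, 10L)
    expect_equal(sc$error_rate, 0)
  }
})
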