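# Toy dataset from hand-applied assignment rules: two EC3 families with
# EC4 group sizes {1.1.1.1: 5, 1.1.1.2: 2, 1.1.1.3: 1} and
# {2.1.3.4: 4, 2.1.3.9: 1}; N = 13.
toy_split_records <- function() {
  sizes <- c("1.1.1.1" = 5, "1.1.1.2" = 2, "1.1.1.3" = 1,
             "2.1.3.4" = 4, "2.1.3.9" = 1)
  tibble::tibble(
    entry = sprintf("T%02d", seq_len(sum(sizes))),
    ec = rep(names(sizes), sizes)
  )
}

test_that("build_unseen_split matches the hand-derived toy assignment", {
  split <- build_unseen_split(toy_split_records(), test_fraction = 0.2)
  # heads 1.1.1.1 and 2.1.3.4 to train; candidates ascending fill to
  # ceiling(0.2 * 13) = 3: groups of sizes 1, 1, 2 all enter test (size 4)
  expect_setequal(unique(split$test$ec), c("1.1.1.3", "2.1.3.9", "1.1.1.2"))
  expect_equal(nrow(split$test), 4L)
  expect_equal(nrow(split$train), 9L)
  expect_setequal(unique(split$train$ec), c("1.1.1.1", "2.1.3.4"))
  prov <- tidy(split)
  expect_equal(prov$reason[prov$ec == "1.1.1.1"], "largest_in_ec3_family")
})

test_that("unseen split invariants hold: disjoint EC4, EC3 coverage, determinism", {
  recs <- make_random_records(7)
  s1 <- build_unseen_split(recs, 0.2)
  s2 <- build_unseen_split(recs, 0.2)
  expect_identical(s1$test$entry, s2$test$entry) # no randomness
  expect_length(intersect(unique(s1$train$ec), unique(s1$test$ec)), 0L)
  expect_true(all(ec_prefix(unique(s1$test$ec), 3) %in%
                    ec_prefix(unique(s1$train$ec), 3)))
  expect_length(intersect(s1$train$entry, s1$test$entry), 0L)
})

test_that("one EC4 group per EC3 family forces an empty test set", {
  recs <- tibble::tibble(entry = sprintf("P%d", 1:6),
                         ec = rep(c("1.1.1.1", "2.2.2.2"), each = 3))
  split <- build_unseen_split(recs, 0.2)
  expect_equal(nrow(split$test), 0L)
  expect_equal(nrow(split$train), 6L)
})

test_that("test_fraction outside (0,1) is rejected", {
  recs <- toy_split_records()
  expect_error(build_unseen_split(recs, 0))
  expect_error(build_unseen_split(recs, 1))
  expect_error(build_seen_split(recs, 1.2))
})

test_that("seen split is seeded, deterministic, and keeps test labels inside train", {
  recs <- tibble::tibble(entry = sprintf("P%02d", 1:10),
                         ec = rep(c("1.1.1.1", "2.2.2.2"), each = 5))
  s1 <- build_seen_split(recs, 0.2, seed = 3)
  s2 <- build_seen_split(recs, 0.2, seed = 3)
  expect_identical(s1$test$entry, s2$test$entry)
  expect_lte(nrow(s1$test), 2L)
  expect_true(all(s1$test$ec %in% s1$train$ec))
  # a label that vanishes from train drops its candidates
  lone <- tibble::tibble(entry = c("A", "B", "C"),
                         ec = c("1.1.1.1", "1.1.1.1", "3.3.3.3"))
  for (sd in 1:20) {
    s <- build_seen_split(lone, 0.34, seed = sd)
    expect_true(all(s$test$ec %in% s$train$ec))
  }
})

test_that("when all records share one EC4 the seen candidates are always retained", {
  recs <- tibble::tibble(entry = sprintf("P%d", 1:8), ec = "5.5.5.5")
  s <- build_seen_split(recs, 0.25, seed = 9)
  expect_equal(nrow(s$test), 2L)
})

test_that("filter_by_similarity applies the identity AND coverage rule", {
  test <- tibble::tibble(entry = c("Q1", "Q2", "Q3"), ec = "1.1.1.1")
  lengths <- c(Q1 = 100L, Q2 = 200L, Q3 = 50L, S1 = 200L, S2 = 300L)
  # Q1: pident 60, alnlen 90, qlen 100 -> coverage_q 0.9 -> removed at >= 50
  # Q2: pident 60, alnlen 90, qlen 200, slen 300 -> cov 0.45/0.30 -> kept
  hits <- tibble::tibble(qseqid = c("Q1", "Q2"), sseqid = c("S1", "S2"),
                         pident = c(60, 60), length = c(90L, 90L))
  out <- filter_by_similarity(test, hits, lengths, identity_threshold = 50)
  expect_setequal(out$entry, c("Q2", "Q3")) # Q3 has no hits -> kept
  # below the identity threshold nothing is removed
  out70 <- filter_by_similarity(test, hits, lengths, identity_threshold = 70)
  expect_equal(nrow(out70), 3L)
})

test_that("subject-side coverage alone can trigger removal", {
  test <- tibble::tibble(entry = "Q1", ec = "1.1.1.1")
  lengths <- c(Q1 = 1000L, S1 = 100L)
  hits <- tibble::tibble(qseqid = "Q1", sseqid = "S1", pident = 80,
                         length = 90L) # cov_q 0.09, cov_s 0.9
  expect_equal(nrow(filter_by_similarity(test, hits, lengths, 50)), 0L)
})

test_that("a hit referencing an unknown id raises an error naming it", {
  test <- tibble::tibble(entry = "Q1", ec = "1.1.1.1")
  hits <- tibble::tibble(qseqid = "Q1", sseqid = "GHOST", pident = 90,
                         length = 10L)
  expect_error(filter_by_similarity(test, hits, c(Q1 = 10L), 50), "GHOST")
})

test_that("filtered test sets are nested across identity thresholds", {
  recs <- make_random_records(21)
  dataset <- generate_dataset(synthetic_spec(seed = 21, dim = 8,
                                             nuisance_dims = 2,
                                             size_range = c(2L, 6L)))
  split <- build_unseen_split(dataset$records, 0.2)
  hits <- generate_hit_table(split$test, split$train, dataset, seed = 5)
  lengths <- stats::setNames(nchar(dataset$records$sequence),
                             dataset$records$entry)
  surv <- lapply(c(50, 30, 10), function(th) {
    filter_by_similarity(split$test, hits, lengths, th)$entry
  })
  expect_true(all(surv[[3]] %in% surv[[2]]))
  expect_true(all(surv[[2]] %in% surv[[1]]))
  expect_true(all(surv[[1]] %in% split$test$entry))
})

test_that("filter_experimental keeps only flagged records and treats missing as false", {
  recs <- tibble::tibble(entry = c("A", "B", "C"), ec = "1.1.1.1",
                         evidence_experimental = c(TRUE, FALSE, TRUE))
  expect_setequal(filter_experimental(recs)$entry, c("A", "C"))
  recs$evidence_experimental <- TRUE
  expect_equal(nrow(filter_experimental(recs)), 3L)
  recs$evidence_experimental <- NA
  expect_equal(nrow(filter_experimental(recs)), 0L)
  expect_equal(nrow(filter_experimental(recs[, c("entry", "ec")])), 0L)
})

test_that("dataset statistics count and conserve", {
  split <- build_unseen_split(toy_split_records(), 0.2)
  st_train <- compute_dataset_stats(split$train)
  st_test <- compute_dataset_stats(split$test)
  expect_equal(st_train$n_unique_ec4, 2L)
  expect_setequal(st_train$per_ec4$n, c(5L, 4L))
  expect_equal(st_test$n_unique_ec4, 3L)
  expect_setequal(st_test$per_ec4$n, c(1L, 1L, 2L))
  expect_equal(sum(st_train$per_ec1$n), nrow(split$train))
  empty <- compute_dataset_stats(tibble::tibble(entry = character(),
                                                ec = character()))
  expect_equal(empty$n_records, 0L)
})

test_that("split manifests and stats serialize", {
  split <- build_unseen_split(toy_split_records(), 0.2)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(split, mpath)
  manifest <- readr::read_tsv(mpath, show_col_types = FALSE)
  expect_equal(nrow(manifest), 13L)
  expect_setequal(unique(manifest$split), c("train", "test"))
  spath <- withr::local_tempfile(fileext = ".json")
  write_dataset_stats(compute_dataset_stats(split$train), spath)
  expect_equal(jsonlite::read_json(spath)$n_records, 9L)
})
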