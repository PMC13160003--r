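unit_rows <- function(m) m / sqrt(rowSums(m^2))

identity_projector <- function(d) {
  p <- init_projector(projection_config(d, d, hidden = integer(0)))
  p$layers[[1]]$W <- diag(d)
  p$layers[[1]]$b <- rep(0, d)
  p
}

test_that("the reference index stores unit projections of every training protein", {
  withr::with_seed(2, {
    base <- matrix(rnorm(6 * 5), 6, 5,
                   dimnames = list(sprintf("T%d", 1:6), NULL))
    labs <- rep(c("1.1.1.1", "2.1.1.1"), 3)
    proj <- init_projector(projection_config(5, 3, seed = 1))
    idx <- build_reference_index(proj, base, labs)
    expect_equal(nrow(idx$vectors), 6L)
    expect_equal(unname(sqrt(rowSums(idx$vectors^2))), rep(1, 6),
                 tolerance = 1e-6)
    expect_identical(project(proj, base), idx$vectors)
  })
})

test_that("nearest-neighbour transfer matches brute force and breaks ties by entry id", {
  d <- 4
  proj <- identity_projector(d)
  withr::with_seed(9, {
    ref <- unit_rows(matrix(rnorm(30 * d), 30))
    rownames(ref) <- sprintf("R%02d", sample(30))
    labs <- paste(sample(1:3, 30, TRUE), sample(1:2, 30, TRUE),
                  sample(1:2, 30, TRUE), sample(1:4, 30, TRUE), sep = ".")
    idx <- build_reference_index(proj, ref, labs)
    q <- unit_rows(matrix(rnorm(10 * d), 10))
    rownames(q) <- sprintf("Q%02d", 1:10)
    pred <- predict_nn(idx, q)
    sims <- q %*% t(ref)
    for (i in 1:10) {
      best <- which(sims[i, ] == max(sims[i, ]))
      expect_equal(pred$predicted_ec[i], labs[best[1]])
      expect_equal(pred$similarity[i], max(sims[i, ]), tolerance = 1e-12)
    }
  })
  # exact tie at k = 1: the smaller entry id wins
  ref <- rbind(c(1, 0), c(1, 0))
  rownames(ref) <- c("B2", "A1")
  idx <- build_reference_index(identity_projector(2), ref, c("1.1.1.1", "2.2.2.2"))
  pred <- predict_nn(idx, c(1, 0))
  expect_equal(pred$neighbor, "A1")
  expect_equal(pred$predicted_ec, "2.2.2.2")
})

test_that("a query equal to a reference vector recovers that reference's label", {
  ref <- unit_rows(matrix(rnorm(12), 4, 3))
  rownames(ref) <- sprintf("R%d", 1:4)
  labs <- c("1.1.1.1", "2.1.1.1", "3.1.1.1", "4.1.1.1")
  idx <- build_reference_index(identity_projector(3), ref, labs)
  pred <- predict_nn(idx, ref[3, ])
  expect_equal(pred$predicted_ec, "3.1.1.1")
  expect_equal(pred$similarity, 1, tolerance = 1e-9)
})

test_that("k-NN voting reduces to 1-NN at k = 1 and takes the plurality otherwise", {
  ref <- rbind(c(1, 0), c(0.98, 0.199), c(0.95, 0.312), c(0, 1))
  ref <- unit_rows(ref)
  rownames(ref) <- c("A", "B", "C", "D")
  labs <- c("1.1.1.1", "2.2.2.2", "2.2.2.2", "3.3.3.3")
  idx <- build_reference_index(identity_projector(2), ref, labs)
  q <- c(1, 0.05)
  expect_equal(predict_nn(idx, q, k = 1)$predicted_ec, "1.1.1.1")
  expect_equal(predict_nn(idx, q, k = 3)$predicted_ec, "2.2.2.2") # 2 votes
  withr::with_seed(3, {
    qs <- unit_rows(matrix(rnorm(10), 5, 2))
    expect_equal(predict_nn(idx, qs, k = 1)$predicted_ec,
                 predict_nn(idx, qs)$predicted_ec)
  })
  expect_error(predict_nn(idx, q, k = 0))
})

test_that("prefix metrics reproduce the hand-computed toy confusion", {
  truths <- c("1.1.1.1", "1.1.2.1", "1.2.1.1", "2.1.1.1")
  preds <- c("1.1.3.1", "1.2.9.9", "1.2.4.4", "2.1.7.7")
  # at depth 2: truths [1.1, 1.1, 1.2, 2.1], preds [1.1, 1.2, 1.2, 2.1]
  m <- prefix_metrics(preds, truths, depth = 2)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$macro_precision, 0.8333, tolerance = 1e-4)
  expect_equal(m$macro_recall, 0.8333, tolerance = 1e-4)
  expect_equal(m$macro_f1, 0.7778, tolerance = 1e-4)
})

test_that("perfect and degenerate prediction sets hit the metric boundaries", {
  truths <- c("1.1.1.1", "2.2.2.2", "3.3.3.3")
  perfect <- prefix_metrics(truths, truths, 3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  # all predictions in one wrong class: zero-division convention -> 0s
  wrong <- prefix_metrics(rep("4.4.4.4", 3), truths, 1)
  expect_equal(wrong$accuracy, 0)
  expect_equal(wrong$macro_precision, 0)
  expect_equal(wrong$macro_recall, 0)
  expect_equal(wrong$macro_f1, 0)
  expect_error(prefix_metrics("1.1.1.1", truths, 1), "length")
})

test_that("accuracy never increases with depth", {
  withr::with_seed(55, {
    for (rep in 1:25) {
      n <- sample(5:40, 1)
      truths <- paste(sample(1:3, n, TRUE), sample(1:2, n, TRUE),
                      sample(1:2, n, TRUE), sample(1:3, n, TRUE), sep = ".")
      preds <- paste(sample(1:3, n, TRUE), sample(1:2, n, TRUE),
                     sample(1:2, n, TRUE), sample(1:3, n, TRUE), sep = ".")
      accs <- vapply(1:4, function(d) prefix_metrics(preds, truths, d)$accuracy,
                     numeric(1))
      expect_true(all(diff(accs) <= 1e-12))
    }
  })
})

test_that("bootstrap metrics are seeded, degenerate on perfect input, and bounded", {
  truths <- rep(c("1.1.1.1", "2.2.2.2"), 10)
  r1 <- bootstrap_metrics(truths, truths, depths = 1:3, n_resamples = 50, seed = 4)
  df <- tibble::as_tibble(r1)
  expect_true(all(df$boot_mean == 1))
  expect_true(all(df$half_width == 0))
  preds <- c(truths[1:15], rep("3.3.3.3", 5))
  r2 <- bootstrap_metrics(preds, truths, depths = 1:2, n_resamples = 100, seed = 7)
  r3 <- bootstrap_metrics(preds, truths, depths = 1:2, n_resamples = 100, seed = 7)
  expect_identical(tibble::as_tibble(r2), tibble::as_tibble(r3))
  df2 <- tibble::as_tibble(r2)
  expect_true(all(df2$ci_lower >= 0 & df2$ci_upper <= 1))
  expect_true(all(df2$half_width >= 0))
  expect_equal(glance(r2)$n_resamples, 100L)
})

test_that("bootstrap half-width shrinks as the test set grows", {
  make_pairs <- function(n) {
    truths <- rep("1.1.1.1", n)
    preds <- truths
    preds[seq_len(round(0.25 * n))] <- "2.1.1.1"
    list(p = preds, t = truths)
  }
  hw <- vapply(c(40, 400), function(n) {
    pr <- make_pairs(n)
    df <- tibble::as_tibble(bootstrap_metrics(pr$p, pr$t, depths = 1,
                                              n_resamples = 200, seed = 1))
    df$half_width[df$metric == "accuracy"]
  }, numeric(1))
  expect_lt(hw[2], hw[1])
})

test_that("predictions and metrics serialize to TSV/JSON", {
  pred <- tibble::tibble(query = c("Q1", "Q2"), predicted_ec = c("1.1.1.1", "2.2.2.2"),
                         neighbor = c("R1", "R2"), similarity = c(0.9, 0.8))
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(pred, tpath)
  back <- readr::read_tsv(tpath, show_col_types = FALSE)
  expect_equal(back$predicted_ec, pred$predicted_ec)
  m <- bootstrap_metrics(c("1.1.1.1", "2.2.2.2"), c("1.1.1.1", "2.2.2.2"),
                         depths = 1:2, n_resamples = 20, seed = 1)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(m, jpath)
  parsed <- jsonlite::read_json(jpath)
  expect_equal(parsed$n_test, 2L)
  expect_true("accuracy" %in% names(parsed$depths[["1"]]))
})
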