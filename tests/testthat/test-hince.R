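unit <- function(v) v / sqrt(sum(v^2))

test_that("instance loss closed forms hold", {
  v <- unit(rnorm(4))
  # single positive, no negatives: numerator equals denominator -> 0
  expect_equal(instance_loss(v, matrix(unit(rnorm(4)), 1), NULL, tau = 0.1), 0,
               tolerance = 1e-12)
  expect_equal(instance_loss(v, matrix(unit(rnorm(4)), 1), NULL, tau = 0.07), 0,
               tolerance = 1e-12)
  # two positives equally similar to the anchor, no negatives -> log 2
  a <- c(1, 0, 0)
  p <- rbind(c(0, 1, 0), c(0, 0, 1))
  for (tau in c(0.05, 0.1, 1, 5)) {
    expect_equal(instance_loss(a, p, NULL, tau), log(2), tolerance = 1e-12)
  }
  # anchor (1,0), positive (1,0), negative (-1,0), tau = 1
  expect_equal(instance_loss(c(1, 0), matrix(c(1, 0), 1), matrix(c(-1, 0), 1), 1),
               log(1 + exp(-2)), tolerance = 1e-12)
  expect_error(instance_loss(a, p[0, , drop = FALSE], NULL, 0.1), "positive")
})

test_that("instance loss matches the scalar oracle and is monotone in positive similarity", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      D <- sample(2:6, 1)
      a <- unit(rnorm(D))
      P <- t(apply(matrix(rnorm(3 * D), 3), 1, unit))
      N <- t(apply(matrix(rnorm(4 * D), 4), 1, unit))
      expect_equal(instance_loss(a, P, N, 0.1), oracle_instance(a, P, N, 0.1),
                   tolerance = 1e-9)
    })
  }
  # pulling a positive closer to the anchor lowers the loss
  a <- c(1, 0)
  N <- matrix(c(0, 1), 1)
  far <- matrix(unit(c(0.2, 1)), 1)
  near <- matrix(unit(c(0.9, 1)), 1)
  expect_lt(instance_loss(a, near, N, 0.1), instance_loss(a, far, N, 0.1))
})

test_that("centroids are exact per-class means at every depth", {
  z <- rbind(unit(c(1, 0)), unit(c(0, 1)))
  sl <- compute_centroids(z, c("1.1.1.1", "1.1.1.2"), 3)
  expect_equal(sl$classes, "1.1.1")
  expect_equal(sl$counts, 2L)
  expect_equal(sl$centroids[1, ], colMeans(z))
  # singleton centroid equals its member
  s1 <- compute_centroids(z[1, , drop = FALSE], "2.2.2.2", 4)
  expect_equal(s1$centroids[1, ], z[1, ])
  # random batch against the scalar-loop oracle at all depths
  withr::with_seed(5, {
    z10 <- t(apply(matrix(rnorm(10 * 4), 10), 1, unit))
    labs <- replicate(10, paste(sample(1:2, 4, replace = TRUE), collapse = "."))
    for (l in 1:4) {
      sl <- compute_centroids(z10, labs, l)
      orc <- oracle_centroids(z10, labs, l)
      for (cl in sl$classes) {
        expect_equal(sl$centroids[cl, ], orc[[cl]]$centroid, tolerance = 1e-12)
        expect_equal(sl$counts[match(cl, sl$classes)], orc[[cl]]$n)
      }
    }
  })
  expect_equal(compute_centroids(matrix(numeric(), 0, 2), character(), 2)$classes,
               character())
})

test_that("leave-one-out centroid drops the anchor and degrades gracefully for singletons", {
  za <- unit(c(1, 0, 0)); zb <- unit(c(0, 1, 1))
  sl <- compute_centroids(rbind(za, zb), c("1.1.1.1", "1.1.1.2"), 3)
  expect_equal(loo_centroid(sl, za, "1.1.1.1"), zb, tolerance = 1e-12)
  s1 <- compute_centroids(matrix(za, 1), "1.1.1.1", 3)
  expect_equal(loo_centroid(s1, za, "1.1.1.1"), za)
  expect_error(loo_centroid(sl, za, "9.9.9.9"), "not present")
  # three members: mean of the other two
  withr::with_seed(8, {
    z3 <- t(apply(matrix(rnorm(9), 3), 1, unit))
    sl3 <- compute_centroids(z3, rep("2.1.3.4", 3), 4)
    expect_equal(loo_centroid(sl3, z3[2, ], "2.1.3.4"),
                 colMeans(z3[c(1, 3), ]), tolerance = 1e-12)
  })
})

test_that("per-depth exemplar loss closed forms and oracle agreement hold", {
  # sole singleton class: LOO centroid equals the centroid, one-term softmax
  v <- unit(rnorm(5))
  s1 <- compute_centroids(matrix(v, 1), "3.2.1.4", 2)
  expect_equal(exemplar_loss_at_depth(v, "3.2.1.4", s1, 0.1), 0, tolerance = 1e-12)
  # sole two-member class of orthogonal unit vectors: (1 - za.zb) / (2 tau)
  za <- c(1, 0); zb <- c(0, 1)
  sl <- compute_centroids(rbind(za, zb), c("1.1.1.1", "1.1.1.2"), 3)
  expect_equal(exemplar_loss_at_depth(za, "1.1.1.1", sl, 0.1), 5, tolerance = 1e-12)
  expect_equal(exemplar_loss_at_depth(za, "1.1.1.1", sl, 0.1),
               oracle_exem_depth(rbind(za, zb), c("1.1.1.1", "1.1.1.2"), 3, 1, 0.1),
               tolerance = 1e-12)
  # two classes, random vectors, all depths vs oracle
  withr::with_seed(12, {
    z <- t(apply(matrix(rnorm(8 * 3), 8), 1, unit))
    labs <- c("1.1.1.1", "1.1.1.1", "1.1.2.1", "1.2.1.1",
              "2.1.1.1", "2.1.1.2", "2.2.1.1", "1.1.1.2")
    for (l in 1:4) {
      sl <- compute_centroids(z, labs, l)
      for (a in c(1, 4, 6)) {
        expect_equal(exemplar_loss_at_depth(z[a, ], labs[a], sl, 0.1),
                     oracle_exem_depth(z, labs, l, a, 0.1), tolerance = 1e-9)
      }
    }
    tab <- compute_centroid_table(z, labs)
    expect_equal(exemplar_loss(z[3, ], labs[3], tab, 0.1),
                 oracle_exem(z, labs, 3, 0.1), tolerance = 1e-9)
  })
})

test_that("depth averaging is the arithmetic mean of per-depth values", {
  withr::with_seed(4, {
    z <- rbind(unit(rnorm(3)), unit(rnorm(3)), unit(rnorm(3)))
    labs <- c("1.1.1.1", "1.1.1.2", "2.1.1.1")
    tab <- compute_centroid_table(z, labs)
    per_depth <- vapply(tab, function(sl) {
      exemplar_loss_at_depth(z[1, ], labs[1], sl, 0.1)
    }, numeric(1))
    expect_equal(exemplar_loss(z[1, ], labs[1], tab, 0.1), mean(per_depth),
                 tolerance = 1e-12)
  })
})

test_that("combined loss reduces to its components at zero weights", {
  b <- make_random_batch(31)
  full <- hince_loss(b$z, b$labels, b$pos, b$neg, loss_weights(1, 1, 0.1))
  only_inst <- hince_loss(b$z, b$labels, b$pos, b$neg, loss_weights(1, 0, 0.1))
  only_exem <- hince_loss(b$z, b$labels, b$pos, b$neg, loss_weights(0, 1, 0.1))
  expect_equal(only_inst$total, only_inst$instance, tolerance = 1e-12)
  expect_equal(only_exem$total, only_exem$exemplar, tolerance = 1e-12)
  expect_equal(full$total, full$instance + full$exemplar, tolerance = 1e-12)
  expect_error(loss_weights(0, 0), "both")
  expect_error(loss_weights(1, 1, tau = 0))
})

test_that("losses stay finite across the temperature range on unit inputs", {
  b <- make_random_batch(77)
  for (tau in c(0.01, 0.1, 1, 10)) {
    res <- hince_loss(b$z, b$labels, b$pos, b$neg, loss_weights(1, 1, tau))
    expect_true(is.finite(res$total))
    expect_true(is.finite(res$instance))
    expect_true(is.finite(res$exemplar))
  }
})
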