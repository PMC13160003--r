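# Independent scalar-loop oracles for the contrastive losses. These are
# deliberately written with plain loops and direct exponentials, sharing no
# code with the package's vectorized implementations.

oracle_prefix <- function(ec, depth) {
  paste(strsplit(ec, ".", fixed = TRUE)[[1]][seq_len(depth)], collapse = ".")
}

oracle_instance <- function(anchor, positives, negatives, tau) {
  num_terms <- numeric(nrow(positives))
  denom <- 0
  all_rows <- rbind(positives, negatives)
  for (u in seq_len(nrow(all_rows))) {
    denom <- denom + exp(sum(anchor * all_rows[u, ]) / tau)
  }
  for (p in seq_len(nrow(positives))) {
    num_terms[p] <- log(exp(sum(anchor * positives[p, ]) / tau) / denom)
  }
  -mean(num_terms)
}

oracle_centroids <- function(z, labels, depth) {
  cls <- vapply(labels, oracle_prefix, character(1), depth = depth)
  out <- list()
  for (cl in unique(cls)) {
    rows <- which(cls == cl)
    cen <- rep(0, ncol(z))
    for (r in rows) cen <- cen + z[r, ]
    out[[cl]] <- list(centroid = cen / length(rows), n = length(rows),
                      members = rows)
  }
  out
}

oracle_loo <- function(z, labels, depth, a) {
  cls <- vapply(labels, oracle_prefix, character(1), depth = depth)
  rows <- which(cls == cls[a])
  if (length(rows) == 1L) return(z[a, ])
  others <- setdiff(rows, a)
  cen <- rep(0, ncol(z))
  for (r in others) cen <- cen + z[r, ]
  cen / length(others)
}

oracle_exem_depth <- function(z, labels, depth, a, tau) {
  cents <- oracle_centroids(z, labels, depth)
  mu_t <- oracle_loo(z, labels, depth, a)
  denom <- 0
  for (cl in names(cents)) {
    denom <- denom + exp(sum(z[a, ] * cents[[cl]]$centroid) / tau)
  }
  -log(exp(sum(z[a, ] * mu_t) / tau) / denom)
}

oracle_exem <- function(z, labels, a, tau) {
  vals <- numeric(4)
  for (l in 1:4) vals[l] <- oracle_exem_depth(z, labels, l, a, tau)
  mean(vals)
}

oracle_hince <- function(z, labels, pos, neg, lambda_inst, lambda_exem, tau) {
  B <- length(labels)
  za <- z[seq_len(B), , drop = FALSE]
  total <- 0
  for (a in seq_len(B)) {
    li <- oracle_instance(z[a, ], z[pos[[a]], , drop = FALSE],
                          z[neg[[a]], , drop = FALSE], tau)
    le <- oracle_exem(za, labels, a, tau)
    total <- total + lambda_inst * li + lambda_exem * le
  }
  total / B
}

# Random contrastive batch with full 4-level labels; every anchor has a
# guaranteed same-label extra row, so positives always exist.
make_random_batch <- function(seed, max_anchors = 16L, max_dim = 8L) {
  withr::with_seed(seed, {
    B <- sample(2:max_anchors, 1L)
    D <- sample(2:max_dim, 1L)
    labels <- replicate(B, paste(sample(1:2, 1L), sample(1:2, 1L),
                                 sample(1:2, 1L), sample(1:3, 1L), sep = "."))
    # force at least two distinct EC1 classes so negatives exist
    labels[1] <- "1.1.1.1"
    labels[2] <- "2.1.1.1"
    m <- 2L * B
    z <- matrix(stats::rnorm(m * D), m, D)
    z <- z / sqrt(rowSums(z^2))
    pool_labels <- c(labels, labels) # row B+a duplicates anchor a's label
    pos <- lapply(seq_len(B), function(a) {
      same <- setdiff(which(pool_labels == labels[a]), a)
      sample(same, min(length(same), sample(1:3, 1L)), replace = FALSE)
    })
    neg <- lapply(seq_len(B), function(a) {
      diffr <- which(pool_labels != labels[a])
      sample(diffr, min(length(diffr), sample(1:4, 1L)), replace = FALSE)
    })
    list(z = z, labels = labels, pos = pos, neg = neg)
  })
}

# Small random hierarchical record set for split fuzzing.
make_random_records <- function(seed) {
  spec <- withr::with_seed(seed, synthetic_spec(
    n_ec1 = sample(1:3, 1L), n_ec2 = sample(1:2, 1L),
    n_ec3 = sample(1:2, 1L), n_ec4 = sample(1:4, 1L),
    size_range = sort(sample(1:8, 2L, replace = TRUE)),
    dim = 4L, nuisance_dims = 1L, seq_length_range = c(10L, 20L),
    seed = seed
  ))
  generate_dataset(spec)$records
}
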