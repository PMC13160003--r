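#' Training configuration
#'
#' Collects the hyperparameters of the contrastive training loop. The sampling
#' counts, shortlist size, hard-negative fraction and refresh interval are
#' engineering defaults exposed for tuning, not canonical values.
#'
#' @param epochs Number of passes over the anchors (>= 1).
#' @param batch_size Anchors per minibatch (>= 1), default 32.
#' @param n_positives Sampled positives per anchor, default 2.
#' @param n_negatives Sampled negatives per anchor, default 8.
#' @param p_hard Probability that a negative is drawn from the anchor's mined
#'   hard-negative class pool rather than uniformly, in `[0, 1]`; default 0.7.
#' @param shortlist_k Distance-map shortlist length per protein, default 20.
#' @param refresh_interval Epochs between distance-map refreshes (>= 1),
#'   default 5.
#' @param learning_rate Adam step size, default 1e-3.
#' @param weights A [loss_weights()] object.
#' @param seed Integer seed controlling all sampling and initialization.
#' @param validation_fraction Fraction of training entries held out (seeded,
#'   stratified by EC4 where class size permits) for monitoring; 0 disables.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, n_positives = 2L,
                         n_negatives = 8L, p_hard = 0.7, shortlist_k = 20L,
                         refresh_interval = 5L, learning_rate = 1e-3,
                         weights = loss_weights(), seed = 1L,
                         validation_fraction = 0) {
  stopifnot(epochs >= 1L, batch_size >= 1L, n_positives >= 1L, n_negatives >= 1L,
            p_hard >= 0, p_hard <= 1, shortlist_k >= 1L, refresh_interval >= 1L,
            learning_rate > 0, inherits(weights, "loss_weights"),
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 n_positives = as.integer(n_positives),
                 n_negatives = as.integer(n_negatives), p_hard = p_hard,
                 shortlist_k = as.integer(shortlist_k),
                 refresh_interval = as.integer(refresh_interval),
                 learning_rate = learning_rate, weights = weights,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

#' Hard-negative distance map
#'
#' For each protein, the `k` most similar proteins carrying a *different* EC4
#' label, ranked by inner product in the current (unit-normalized) projected
#' space; ties are broken by entry-id order. The map is the mined pool from
#' which hard negatives are preferentially drawn, and is refreshed
#' periodically because the learned space drifts during training.
#'
#' @param projected Numeric matrix of unit row vectors with rownames = entry
#'   ids.
#' @param labels Canonical EC4 strings aligned with rows.
#' @param k Shortlist length; if fewer different-label proteins exist, the
#'   shortlist is all of them.
#' @return A list of class `distance_map`: `entries`, `labels`, `shortlist`
#'   (list of integer index vectors, descending similarity), `shortlist_labels`
#'   (EC4 labels of shortlist members), `epoch` (refresh stamp, set by the
#'   training loop; `NA` when built standalone).
#' @export
build_distance_map <- function(projected, labels, k) {
  stopifnot(is.matrix(projected), nrow(projected) == length(labels))
  n <- nrow(projected)
  entries <- rownames(projected)
  if (is.null(entries)) entries <- as.character(seq_len(n))
  sims <- tcrossprod(projected)
  ord_entry <- order(entries)
  rank_entry <- integer(n)
  rank_entry[ord_entry] <- seq_len(n)
  shortlist <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- which(labels != labels[i])
    if (length(cand) == 0L) {
      shortlist[[i]] <- integer(0)
      next
    }
    # descending similarity, ties by entry-id order
    o <- cand[order(-sims[i, cand], rank_entry[cand])]
    shortlist[[i]] <- o[seq_len(min(k, length(o)))]
  }
  structure(list(entries = entries, labels = labels, shortlist = shortlist,
                 shortlist_labels = lapply(shortlist, function(s) labels[s]),
                 epoch = NA_integer_),
            class = "distance_map")
}

#' Mask-augment a sequence
#'
#' Replaces one seeded-random residue with the mask character `"*"`, producing
#' a near-duplicate view whose recomputed embedding serves as a positive for
#' proteins whose EC4 class has no other member. The output always differs
#' from the input at exactly one position.
#'
#' @param sequence Single non-empty amino-acid string.
#' @param seed Integer seed choosing the position.
#' @return The masked sequence (same length).
#' @export
mask_augment <- function(sequence, seed = 1L) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) < 1L) {
    rlang::abort("`sequence` must be a single non-empty string.")
  }
  pos <- withr::with_seed(seed, sample.int(nchar(sequence), 1L))
  paste0(substr(sequence, 1L, pos - 1L), "*",
         substr(sequence, pos + 1L, nchar(sequence)))
}

# Sample positive/negative index sets for a vector of anchor indices.
# pool_labels covers base rows 1..n plus augmented rows; anchors index base rows.
# Augmented rows are positives-only: excluded from negative pools.
sample_anchor_sets <- function(anchors, pool_labels, n_base, distance_map, config) {
  by_label <- split(seq_along(pool_labels), pool_labels)
  base_idx <- seq_len(n_base)
  positives <- vector("list", length(anchors))
  negatives <- vector("list", length(anchors))
  for (j in seq_along(anchors)) {
    a <- anchors[j]
    lab <- pool_labels[a]
    pos_pool <- setdiff(by_label[[lab]], a)
    if (length(pos_pool) == 0L) {
      rlang::abort(sprintf(
        "EC4 class %s has a single member and no augmented view; register a mask-augmented positive (see mask_augment()).",
        lab))
    }
    positives[[j]] <- pos_pool[sample.int(length(pos_pool), config$n_positives,
                                          replace = TRUE)]
    hard_classes <- unique(distance_map$shortlist_labels[[a]])
    neg_pool_all <- base_idx[pool_labels[base_idx] != lab]
    negatives[[j]] <- vapply(seq_len(config$n_negatives), function(i) {
      if (length(hard_classes) > 0L && stats::runif(1) < config$p_hard) {
        cls <- hard_classes[sample.int(length(hard_classes), 1L)]
        pool <- by_label[[cls]]
        pool <- pool[pool <= n_base]
        pool[sample.int(length(pool), 1L)]
      } else {
        neg_pool_all[sample.int(length(neg_pool_all), 1L)]
      }
    }, integer(1))
  }
  list(positives = positives, negatives = negatives)
}

#' Sample a contrastive batch
#'
#' Draws, for each anchor, `n_positives` same-EC4 indices (uniform, anchor
#' excluded, with replacement) and `n_negatives` different-EC4 indices; each
#' negative independently comes from the anchor's mined hard-negative class
#' pool (a uniformly chosen shortlist class, then a uniform member of that
#' class) with probability `p_hard`, otherwise uniformly from all
#' different-EC4 proteins. Sampling is driven by the current RNG state, so
#' seed the session (or use [withr::with_seed()]) for reproducibility.
#'
#' @param labels Canonical EC4 strings for all proteins (base rows).
#' @param distance_map A [build_distance_map()] result over the same rows.
#' @param config A [train_config()].
#' @param anchors Integer indices of the anchor rows (default: all).
#' @return A list with `anchors`, `positives` and `negatives` (index lists).
#' @export
sample_batch <- function(labels, distance_map, config, anchors = seq_along(labels)) {
  sets <- sample_anchor_sets(anchors, labels, length(labels), distance_map, config)
  list(anchors = anchors, positives = sets$positives, negatives = sets$negatives)
}

#' In-memory embedding provider
#'
#' Wraps lookup tables into the provider contract used by [hince_train()]:
#' `base_embedding(entry)` returns the stored base vector and
#' `embed_sequence(sequence)` maps a (possibly mask-augmented) sequence to an
#' embedding. Both must be deterministic.
#'
#' @param base_embedding Function `entry id -> numeric vector`.
#' @param embed_sequence Function `sequence string -> numeric vector`.
#' @return A list of class `embedding_provider`.
#' @export
embedding_provider <- function(base_embedding, embed_sequence) {
  stopifnot(is.function(base_embedding), is.function(embed_sequence))
  structure(list(base_embedding = base_embedding, embed_sequence = embed_sequence),
            class = "embedding_provider")
}

#' Train the projection head with the hierarchical contrastive objective
#'
#' Optimizes an MLP projection head over frozen base embeddings with Adam,
#' minimizing the combined instance + hierarchical exemplar loss
#' ([hince_loss()]). Each epoch shuffles all training proteins into anchor
#' minibatches; positives and negatives are re-sampled fresh every iteration,
#' with negatives biased toward mined hard-negative classes from a distance
#' map that is rebuilt every `refresh_interval` epochs in the current
#' projected space. Anchors, positives and negatives are all projected with
#' the current parameters in the same forward pass.
#'
#' Before training, every protein whose EC4 class has a single member gets an
#' augmented positive view: its sequence is mask-augmented
#' ([mask_augment()]) and embedded through the provider, so singleton classes
#' contribute a non-trivial positive signal in every epoch. Augmented views
#' are used only as positives (never as anchors, negatives or centroid
#' members).
#'
#' The run is fully reproducible: all randomness derives from `config$seed`.
#'
#' @param base Numeric matrix of base embeddings with rownames = entry ids.
#' @param labels Canonical EC4 strings aligned with rows of `base`.
#' @param sequences Named character vector of amino-acid sequences (needed for
#'   singleton-class augmentation; may be `NULL` if no singletons exist).
#' @param provider An [embedding_provider()] used to embed masked views.
#' @param config A [train_config()].
#' @param projector Optional pre-initialized projector; by default one is
#'   created from [projection_config()] with `output_dim = min(128, d)` and
#'   the config seed.
#' @return An object of class `hince_fit`: `projector` (trained), `log`
#'   (tibble: epoch, loss, instance, exemplar, refreshed), `config`,
#'   `n_augmented`.
#' @export
hince_train <- function(base, labels, sequences = NULL, provider = NULL,
                        config = train_config(), projector = NULL) {
  stopifnot(is.matrix(base), nrow(base) == length(labels))
  n <- nrow(base)
  entries <- rownames(base)
  if (is.null(entries)) {
    entries <- as.character(seq_len(n))
    rownames(base) <- entries
  }
  d <- ncol(base)
  if (is.null(projector)) {
    projector <- init_projector(projection_config(
      input_dim = d, output_dim = min(128L, d), seed = config$seed))
  }

  # Augmented positive views for singleton EC4 classes.
  sizes <- table(labels)
  singleton <- which(labels %in% names(sizes)[sizes == 1L])
  aug_base <- NULL
  if (length(singleton) > 0L) {
    if (is.null(sequences) || is.null(provider)) {
      rlang::abort("Singleton EC4 classes present: `sequences` and `provider` are required for mask augmentation.")
    }
    aug_base <- t(vapply(seq_along(singleton), function(i) {
      id <- entries[singleton[i]]
      seq <- sequences[[id]]
      if (is.null(seq) || is.na(seq)) {
        rlang::abort(sprintf("No sequence available for singleton entry %s.", id))
      }
      masked <- mask_augment(seq, seed = config$seed + i)
      provider$embed_sequence(masked)
    }, numeric(d)))
    rownames(aug_base) <- paste0(entries[singleton], "__aug")
  }
  all_base <- rbind(base, aug_base)
  pool_labels <- c(labels, labels[singleton])

  state <- NULL # Adam moments
  fit_log <- vector("list", config$epochs)
  dm <- NULL
  dm_epoch <- NA_integer_

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      refreshed <- FALSE
      if (is.null(dm) || (epoch - dm_epoch) >= config$refresh_interval) {
        proj <- project(projector, base)
        dm <- build_distance_map(proj, labels, config$shortlist_k)
        dm$epoch <- epoch
        dm_epoch <- epoch
        refreshed <- TRUE
      }
      order_idx <- sample.int(n)
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
      ep_loss <- 0; ep_inst <- 0; ep_exem <- 0; n_anchor <- 0
      for (anchors in batches) {
        sets <- sample_anchor_sets(anchors, pool_labels, n, dm, config)
        used <- unique(c(anchors, unlist(sets$positives), unlist(sets$negatives)))
        row_of <- match(seq_len(nrow(all_base)), used)
        # batch rows: anchors first, then the remaining referenced embeddings
        extra <- setdiff(used, anchors)
        batch_rows <- c(anchors, extra)
        lookup <- integer(nrow(all_base))
        lookup[batch_rows] <- seq_along(batch_rows)
        x <- all_base[batch_rows, , drop = FALSE]
        pos <- lapply(sets$positives, function(p) lookup[p])
        neg <- lapply(sets$negatives, function(p) lookup[p])

        fwd <- projector_forward(projector, x)
        loss <- hince_loss(fwd$z, labels[anchors], pos, neg,
                           weights = config$weights, grad = TRUE)
        back <- projector_backward(projector, fwd, loss$grad)
        upd <- adam_update(projector, back$param, state, config$learning_rate)
        projector <- upd$projector
        state <- upd$state

        nb <- length(anchors)
        ep_loss <- ep_loss + loss$total * nb
        ep_inst <- ep_inst + loss$instance * nb
        ep_exem <- ep_exem + loss$exemplar * nb
        n_anchor <- n_anchor + nb
      }
      fit_log[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = ep_loss / n_anchor,
        instance = ep_inst / n_anchor, exemplar = ep_exem / n_anchor,
        refreshed = refreshed
      )
    }
  })
  structure(list(projector = projector,
                 log = dplyr::bind_rows(fit_log),
                 config = config,
                 n_augmented = length(singleton)),
            class = "hince_fit")
}

# One Adam step over all layer parameters.
adam_update <- function(projector, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  L <- length(projector$layers)
  if (is.null(state)) {
    state <- list(t = 0L, m = purrr::map(projector$layers, function(l) {
      list(W = l$W * 0, b = l$b * 0)
    }), v = purrr::map(projector$layers, function(l) {
      list(W = l$W * 0, b = l$b * 0)
    }))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_len(L)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[paste0("d", p)]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[p]] / bc1
      vhat <- state$v[[i]][[p]] / bc2
      projector$layers[[i]][[p]] <- projector$layers[[i]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(projector = projector, state = state)
}

#' @export
print.hince_fit <- function(x, ...) {
  cat(sprintf("Hierarchical contrastive fit: %d epochs, final loss %.4f (instance %.4f, exemplar %.4f)\n",
              nrow(x$log), x$log$loss[nrow(x$log)],
              x$log$instance[nrow(x$log)], x$log$exemplar[nrow(x$log)]))
  if (x$n_augmented > 0) cat(" ", x$n_augmented, "singleton class(es) mask-augmented\n")
  invisible(x)
}

#' Per-epoch training log
#' @param x A `hince_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch.
#' @method tidy hince_fit
#' @export
tidy.hince_fit <- function(x, ...) x$log

#' One-row training summary
#' @param x A `hince_fit`.
#' @param ... Unused.
#' @return One-row tibble: first/final loss, epochs, augmented count.
#' @method glance hince_fit
#' @export
glance.hince_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    first_loss = x$log$loss[1L],
    final_loss = x$log$loss[nrow(x$log)],
    n_augmented = x$n_augmented
  )
}

#' Write a training log as JSON
#' @param fit A `hince_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(fit, path) {
  stopifnot(inherits(fit, "hince_fit"))
  jsonlite::write_json(list(config = list(
    epochs = fit$config$epochs, batch_size = fit$config$batch_size,
    seed = fit$config$seed), log = fit$log),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
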