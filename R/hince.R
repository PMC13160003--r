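#' Loss weights for the hierarchical contrastive objective
#'
#' @param lambda_inst Weight of the instance-level supervised contrastive
#'   term (>= 0), default 1.
#' @param lambda_exem Weight of the hierarchical exemplar NCE term (>= 0),
#'   default 1. At least one weight must be positive.
#' @param tau Softmax temperature (> 0), default 0.1; smaller values sharpen
#'   the similarity distribution.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_inst = 1, lambda_exem = 1, tau = 0.1) {
  if (lambda_inst < 0 || lambda_exem < 0 || (lambda_inst == 0 && lambda_exem == 0)) {
    rlang::abort("Need lambda_inst, lambda_exem >= 0 and not both zero.")
  }
  if (tau <= 0) rlang::abort("`tau` must be positive.")
  structure(list(lambda_inst = lambda_inst, lambda_exem = lambda_exem, tau = tau),
            class = "loss_weights")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Instance-level supervised contrastive loss for one anchor
#'
#' For an anchor \eqn{z_a} with sampled positives \eqn{P} (same EC4) and
#' negatives \eqn{N} (different EC4), with \eqn{S = P \cup N}:
#' \deqn{L = -\frac{1}{|P|}\sum_{p \in P} \log
#'   \frac{\exp(z_a^\top z_p/\tau)}{\sum_{u \in S}\exp(z_a^\top z_u/\tau)}}
#' computed with overflow-safe log-sum-exp.
#'
#' @param anchor Numeric unit vector.
#' @param positives Matrix of positive embeddings (rows), at least one row.
#' @param negatives Matrix of negative embeddings (rows) or `NULL`.
#' @param tau Temperature (> 0).
#' @return Non-negative scalar loss.
#' @export
instance_loss <- function(anchor, positives, negatives = NULL, tau = 0.1) {
  if (is.null(dim(positives))) positives <- matrix(positives, nrow = 1L)
  if (!is.null(negatives) && is.null(dim(negatives))) negatives <- matrix(negatives, nrow = 1L)
  if (nrow(positives) < 1L) rlang::abort("At least one positive is required.")
  s_pos <- as.numeric(positives %*% anchor) / tau
  s_neg <- if (is.null(negatives) || nrow(negatives) == 0L) numeric(0) else {
    as.numeric(negatives %*% anchor) / tau
  }
  lse <- logsumexp(c(s_pos, s_neg))
  -mean(s_pos) + lse
}

#' Per-depth class centroids of a batch
#'
#' Groups embeddings by the depth-`depth` prefix of their EC labels and
#' returns the arithmetic mean of each group (no renormalization: centroids
#' generally lie inside the unit ball).
#'
#' @param embeddings Numeric matrix, one embedding per row.
#' @param labels Character vector of canonical EC4 strings, aligned with rows.
#' @param depth Prefix depth in 1..4.
#' @return A list of class `centroid_slice`: `depth`, `classes` (character),
#'   `counts` (integer), `centroids` (class x dim matrix, rows named by
#'   class), `membership` (class index per input row).
#' @export
compute_centroids <- function(embeddings, labels, depth) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  stopifnot(nrow(embeddings) == length(labels))
  if (length(labels) == 0L) {
    return(structure(list(depth = depth, classes = character(), counts = integer(),
                          centroids = matrix(numeric(), 0L, ncol(embeddings)),
                          membership = integer()),
                     class = "centroid_slice"))
  }
  cls <- ec_prefix(labels, depth)
  f <- factor(cls, levels = unique(cls))
  sums <- rowsum(embeddings, f)
  counts <- as.integer(tabulate(f, nbins = nlevels(f)))
  centroids <- sums / counts
  rownames(centroids) <- levels(f)
  structure(list(depth = depth, classes = levels(f), counts = counts,
                 centroids = centroids, membership = as.integer(f)),
            class = "centroid_slice")
}

#' Centroid table across all four EC depths
#'
#' @inheritParams compute_centroids
#' @return A list of four `centroid_slice` objects, depths 1..4.
#' @export
compute_centroid_table <- function(embeddings, labels) {
  lapply(1:4, function(l) compute_centroids(embeddings, labels, l))
}

#' Leave-one-out class centroid
#'
#' The class mean recomputed without the anchor, preventing trivial
#' self-attraction: \eqn{(\sum_j z_j - z_a)/(n-1)} when the anchor's class has
#' \eqn{n > 1} members, otherwise the full centroid (which then equals the
#' anchor itself).
#'
#' @param slice A `centroid_slice` from [compute_centroids()] built over a
#'   batch containing the anchor.
#' @param anchor Numeric vector: the anchor embedding (a member of its class).
#' @param anchor_label Canonical EC4 string of the anchor.
#' @return The leave-one-out centroid vector.
#' @export
loo_centroid <- function(slice, anchor, anchor_label) {
  cls <- ec_prefix(anchor_label, slice$depth)
  ci <- match(cls, slice$classes)
  if (is.na(ci)) {
    rlang::abort(sprintf("Anchor class %s not present in the centroid table.", cls))
  }
  n <- slice$counts[ci]
  if (n > 1L) {
    (slice$centroids[ci, ] * n - anchor) / (n - 1)
  } else {
    slice$centroids[ci, ]
  }
}

#' Exemplar NCE loss at one hierarchy depth
#'
#' Softmax classification of the anchor against all class centroids at the
#' given depth. The numerator uses the anchor class's leave-one-out centroid
#' \eqn{\tilde\mu}; the denominator sums full centroids over every depth-level
#' class in the table, including the anchor's own class:
#' \deqn{L = -\log\frac{\exp(z_a^\top \tilde\mu_{c_a}/\tau)}
#'   {\sum_c \exp(z_a^\top \mu_c/\tau)}}
#'
#' @param anchor Anchor embedding (a member of its class in `slice`).
#' @param anchor_label Canonical EC4 string of the anchor.
#' @param slice A `centroid_slice` at the desired depth.
#' @param tau Temperature (> 0).
#' @param loo_denominator If `TRUE`, the anchor class's denominator term also
#'   uses the leave-one-out centroid. Default `FALSE` (denominator exactly as
#'   defined, with the full centroid); the switch is an alternative
#'   interpretation, not the reference behaviour.
#' @return Scalar loss (may be negative for unnormalized centroids).
#' @export
exemplar_loss_at_depth <- function(anchor, anchor_label, slice, tau = 0.1,
                                   loo_denominator = FALSE) {
  cls <- ec_prefix(anchor_label, slice$depth)
  ci <- match(cls, slice$classes)
  if (is.na(ci)) {
    rlang::abort(sprintf("Anchor class %s not present in the centroid table.", cls))
  }
  mu_t <- loo_centroid(slice, anchor, anchor_label)
  logits <- as.numeric(slice$centroids %*% anchor) / tau
  if (loo_denominator) logits[ci] <- sum(anchor * mu_t) / tau
  -sum(anchor * mu_t) / tau + logsumexp(logits)
}

#' Depth-averaged exemplar NCE loss
#'
#' Arithmetic mean of [exemplar_loss_at_depth()] over depths 1..4, pulling the
#' anchor toward the centroid of its EC1, EC2, EC3 and EC4 classes while
#' separating it from centroids of other classes at each depth.
#'
#' @param anchor Anchor embedding.
#' @param anchor_label Canonical EC4 string.
#' @param table A four-slice centroid table from [compute_centroid_table()].
#' @inheritParams exemplar_loss_at_depth
#' @return Scalar loss.
#' @export
exemplar_loss <- function(anchor, anchor_label, table, tau = 0.1,
                          loo_denominator = FALSE) {
  mean(vapply(table, function(slice) {
    exemplar_loss_at_depth(anchor, anchor_label, slice, tau, loo_denominator)
  }, numeric(1)))
}

#' Combined hierarchical contrastive (HiNCE) loss over a batch
#'
#' Every row `1..B` of `z` with a label in `labels` is an anchor; additional
#' rows of `z` (beyond `B`) may be referenced by the positive/negative index
#' sets but do not enter the centroids, which are recomputed from the batch's
#' anchor embeddings at every call. The total is
#' \deqn{\frac{1}{B}\sum_a \lambda_{inst} L_{inst}(a) +
#'       \lambda_{exem} L_{exem}(a)}
#' with \eqn{L_{exem}} the depth average of the exemplar NCE terms.
#'
#' When `grad = TRUE` the exact analytic gradient of the total with respect to
#' every row of `z` is returned alongside the value; it accounts for each
#' embedding's role as anchor, sampled positive/negative, centroid member and
#' leave-one-out contributor.
#'
#' @param z Numeric matrix of embeddings (rows); rows `1..length(labels)` are
#'   the anchors.
#' @param labels Canonical EC4 strings for the anchor rows.
#' @param positives List (one element per anchor) of integer row indices into
#'   `z`: sampled same-EC4 positives (anchor excluded); each non-empty.
#' @param negatives List of integer row indices per anchor: different-EC4
#'   negatives (may be empty).
#' @param weights A [loss_weights()] object.
#' @param grad If `TRUE`, also return the gradient matrix (same shape as `z`).
#' @return A list with `total`, `instance` and `exemplar` (the two component
#'   means over anchors), `per_anchor` (tibble of per-anchor terms) and, if
#'   requested, `grad`.
#' @export
hince_loss <- function(z, labels, positives, negatives, weights = loss_weights(),
                       grad = FALSE) {
  stopifnot(is.matrix(z))
  B <- length(labels)
  if (B < 1L || nrow(z) < B) rlang::abort("Need at least one anchor row in `z`.")
  if (length(positives) != B || length(negatives) != B) {
    rlang::abort("`positives` and `negatives` must have one element per anchor.")
  }
  tau <- weights$tau
  za <- z[seq_len(B), , drop = FALSE]
  table <- compute_centroid_table(za, labels)
  # per-depth logits of every anchor against all full centroids
  depth_logits <- lapply(table, function(s) za %*% t(s$centroids) / tau)

  G <- if (grad) matrix(0, nrow(z), ncol(z)) else NULL
  inst_vals <- numeric(B)
  exem_vals <- numeric(B)
  s_inst <- weights$lambda_inst / B
  s_exem <- weights$lambda_exem / (B * 4)

  for (a in seq_len(B)) {
    P <- positives[[a]]
    N <- negatives[[a]]
    if (length(P) < 1L) {
      rlang::abort(sprintf("Anchor %d has no positives; every anchor needs at least one.", a))
    }
    S <- c(P, N)
    if (weights$lambda_inst > 0 || grad) {
      sims <- as.numeric(z[S, , drop = FALSE] %*% za[a, ]) / tau
      lse <- logsumexp(sims)
      inst_vals[a] <- -mean(sims[seq_along(P)]) + lse
      if (grad && weights$lambda_inst > 0) {
        w <- exp(sims - lse)
        coef <- (w - c(rep(1 / length(P), length(P)), rep(0, length(N)))) / tau
        G[a, ] <- G[a, ] + s_inst * as.numeric(crossprod(z[S, , drop = FALSE], coef))
        for (j in seq_along(S)) {
          G[S[j], ] <- G[S[j], ] + s_inst * coef[j] * za[a, ]
        }
      }
    }
    # exemplar term, averaged over depths
    ex_sum <- 0
    for (l in 1:4) {
      s <- table[[l]]
      ci <- s$membership[a]
      n <- s$counts[ci]
      mu_t <- if (n > 1L) (s$centroids[ci, ] * n - za[a, ]) / (n - 1) else s$centroids[ci, ]
      logits <- depth_logits[[l]][a, ]
      lse <- logsumexp(logits)
      num <- sum(za[a, ] * mu_t) / tau
      ex_sum <- ex_sum + (-num + lse)
      if (grad && weights$lambda_exem > 0) {
        # numerator -z_a . mu_t / tau; mu_t = (sum - z_a)/(n-1) has zero
        # derivative in z_a because the class sum contains z_a itself
        if (n > 1L) {
          G[a, ] <- G[a, ] - s_exem * mu_t / tau
          mem <- setdiff(which(s$membership == ci), a)
          if (length(mem) > 0L) {
            G[mem, ] <- G[mem, , drop = FALSE] +
              outer(rep(-s_exem / ((n - 1) * tau), length(mem)), za[a, ])
          }
        } else {
          G[a, ] <- G[a, ] - s_exem * 2 * za[a, ] / tau
        }
        # denominator log-sum-exp over full centroids
        w <- exp(logits - lse)
        G[a, ] <- G[a, ] + s_exem * as.numeric(crossprod(s$centroids, w)) / tau
        v <- w[s$membership] / (s$counts[s$membership] * tau)
        G[seq_len(B), ] <- G[seq_len(B), ] + s_exem * outer(v, za[a, ])
      }
    }
    exem_vals[a] <- ex_sum / 4
  }
  out <- list(
    total = weights$lambda_inst * mean(inst_vals) + weights$lambda_exem * mean(exem_vals),
    instance = mean(inst_vals),
    exemplar = mean(exem_vals),
    per_anchor = tibble::tibble(anchor = seq_len(B), instance = inst_vals,
                                exemplar = exem_vals)
  )
  if (grad) out$grad <- G
  out
}
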