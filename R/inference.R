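#' Build a nearest-neighbour reference index
#'
#' Projects all training embeddings with a trained head and stores the unit
#' vectors with their EC4 labels; queries are answered by cosine similarity
#' (inner product of unit vectors).
#'
#' @param projector A trained `projector`.
#' @param base Numeric matrix of base training embeddings, rownames = entry
#'   ids.
#' @param labels Canonical EC4 strings aligned with rows.
#' @return A list of class `reference_index`: `vectors` (unit-row matrix),
#'   `labels`, `entries`, `projector`.
#' @export
build_reference_index <- function(projector, base, labels) {
  stopifnot(is.matrix(base), nrow(base) == length(labels))
  vectors <- project(projector, base)
  entries <- rownames(base)
  if (is.null(entries)) entries <- as.character(seq_len(nrow(base)))
  structure(list(vectors = vectors, labels = labels, entries = entries,
                 projector = projector),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("Reference index: %d proteins, %d unique EC4, dim %d\n",
              nrow(x$vectors), length(unique(x$labels)), ncol(x$vectors)))
  invisible(x)
}

#' Nearest-neighbour EC label transfer
#'
#' Projects each query and assigns it the EC4 label of its most similar
#' training protein in the learned space (`k = 1`), or the plurality label of
#' its `k` nearest neighbours. Ties at `k = 1` go to the smallest entry id;
#' vote ties are broken by the summed similarity of each candidate label,
#' then by smallest entry id among the tied labels' neighbours.
#'
#' @param index A [build_reference_index()] result.
#' @param queries Numeric matrix of base query embeddings (rows, rownames =
#'   query ids) or a single vector.
#' @param k Number of neighbours to vote over (>= 1), default 1.
#' @return A tibble with one row per query: `query`, `predicted_ec`,
#'   `neighbor` (nearest supporting entry), `similarity` (cosine in [-1, 1]).
#' @export
predict_nn <- function(index, queries, k = 1L) {
  stopifnot(inherits(index, "reference_index"))
  if (nrow(index$vectors) == 0L) rlang::abort("Reference index is empty.")
  if (k < 1L) rlang::abort("`k` must be >= 1.")
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1L)
  qz <- project(index$projector, queries)
  qids <- rownames(queries)
  if (is.null(qids)) qids <- as.character(seq_len(nrow(queries)))
  sims <- qz %*% t(index$vectors) # n_query x n_ref
  n_ref <- ncol(sims)
  rank_entry <- integer(n_ref)
  rank_entry[order(index$entries)] <- seq_len(n_ref)
  k_eff <- min(k, n_ref)

  res <- purrr::map(seq_len(nrow(qz)), function(i) {
    s <- sims[i, ]
    o <- order(-s, rank_entry)[seq_len(k_eff)]
    if (k_eff == 1L) {
      j <- o[1L]
      return(tibble::tibble(query = qids[i], predicted_ec = index$labels[j],
                            neighbor = index$entries[j], similarity = unname(s[j])))
    }
    votes <- table(index$labels[o])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(lb) sum(s[o][index$labels[o] == lb]), numeric(1))
      top <- top[sums == max(sums)]
      if (length(top) > 1L) {
        first_rank <- vapply(top, function(lb) {
          min(rank_entry[o][index$labels[o] == lb])
        }, numeric(1))
        top <- top[which.min(first_rank)]
      } else {
        top <- top[1L]
      }
    }
    in_lab <- o[index$labels[o] == top[1L]]
    j <- in_lab[order(-s[in_lab], rank_entry[in_lab])][1L]
    tibble::tibble(query = qids[i], predicted_ec = top[1L],
                   neighbor = index$entries[j], similarity = unname(s[j]))
  })
  dplyr::bind_rows(res)
}

#' Prefix-level accuracy and macro precision/recall/F1
#'
#' Truncates predicted and ground-truth EC labels to their depth-`depth`
#' prefixes and scores the induced multiclass problem. Accuracy is the
#' fraction of matching prefixes. Per-class precision, recall and F1 are
#' computed over the union of classes occurring in the truths or the
#' predictions (so spurious predicted classes are penalized), with the
#' zero-division convention P, R or F1 = 0 when a denominator is zero; macro
#' metrics are unweighted means over those classes and F1 is the per-class
#' harmonic mean of precision and recall.
#'
#' @param predictions Character vector of predicted canonical EC strings (at
#'   least `depth` fields).
#' @param truths Character vector of ground-truth EC strings, same length.
#' @param depth Prefix depth in 1..4.
#' @param class_set `"union"` (default) or `"truth"`: which classes enter the
#'   macro average.
#' @return A one-row tibble: `depth`, `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `n`.
#' @export
prefix_metrics <- function(predictions, truths, depth, class_set = c("union", "truth")) {
  class_set <- match.arg(class_set)
  if (length(predictions) != length(truths)) {
    rlang::abort("`predictions` and `truths` must have the same length.")
  }
  pred_p <- ec_prefix(predictions, depth)
  true_p <- ec_prefix(truths, depth)
  classes <- switch(class_set,
                    union = sort(unique(c(pred_p, true_p))),
                    truth = sort(unique(true_p)))
  acc <- mean(pred_p == true_p)
  per_class <- purrr::map(classes, function(cl) {
    tp <- sum(pred_p == cl & true_p == cl)
    fp <- sum(pred_p == cl & true_p != cl)
    fn <- sum(pred_p != cl & true_p == cl)
    p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f1 = f1)
  })
  pc <- do.call(rbind, per_class)
  tibble::tibble(
    depth = as.integer(depth),
    accuracy = acc,
    macro_precision = mean(pc[, "p"]),
    macro_recall = mean(pc[, "r"]),
    macro_f1 = mean(pc[, "f1"]),
    n = length(truths)
  )
}

#' Bootstrap prefix metrics with confidence intervals
#'
#' Resamples (prediction, truth) pairs with replacement `n_resamples` times
#' and reports, per depth and metric, the point estimate on the original
#' sample, the bootstrap mean, and the percentile confidence interval at the
#' requested level summarized as a half-width `(upper - lower) / 2` — the
#' "mean +/- half-width" convention.
#'
#' @inheritParams prefix_metrics
#' @param depths Integer vector of prefix depths to evaluate, default `1:3`.
#' @param n_resamples Number of bootstrap resamples, default 1000.
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed; the same seed reproduces the report exactly.
#' @return An object of class `ec_metrics`: a tibble with columns `depth`,
#'   `metric`, `estimate`, `boot_mean`, `ci_lower`, `ci_upper`, `half_width`,
#'   plus attributes `n_test`, `n_resamples`, `level`, `seed`.
#' @export
bootstrap_metrics <- function(predictions, truths, depths = 1:3,
                              n_resamples = 1000L, level = 0.95, seed = 1L,
                              class_set = c("union", "truth")) {
  class_set <- match.arg(class_set)
  n <- length(truths)
  stopifnot(n >= 1L, length(predictions) == n)
  point <- dplyr::bind_rows(lapply(depths, function(d) {
    prefix_metrics(predictions, truths, d, class_set)
  }))

  boot <- withr::with_seed(seed, {
    lapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      dplyr::bind_rows(lapply(depths, function(d) {
        prefix_metrics(predictions[idx], truths[idx], d, class_set)
      }))
    })
  })
  boot_df <- dplyr::bind_rows(boot)

  metric_cols <- c("accuracy", "macro_precision", "macro_recall", "macro_f1")
  alpha <- (1 - level) / 2
  long_point <- point |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "estimate") |>
    dplyr::select("depth", "metric", "estimate")
  long_boot <- boot_df |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$depth, .data$metric) |>
    dplyr::summarise(
      boot_mean = mean(.data$value),
      ci_lower = stats::quantile(.data$value, alpha, names = FALSE),
      ci_upper = stats::quantile(.data$value, 1 - alpha, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(half_width = (.data$ci_upper - .data$ci_lower) / 2)
  out <- dplyr::left_join(long_point, long_boot, by = c("depth", "metric")) |>
    dplyr::arrange(.data$depth, .data$metric)
  structure(out, class = c("ec_metrics", class(out)),
            n_test = n, n_resamples = as.integer(n_resamples),
            level = level, seed = as.integer(seed))
}

#' @export
print.ec_metrics <- function(x, ...) {
  cat(sprintf("Prefix metrics on %d test proteins (%d bootstrap resamples, %.0f%% CI)\n",
              attr(x, "n_test"), attr(x, "n_resamples"), 100 * attr(x, "level")))
  df <- tibble::as_tibble(x) |>
    dplyr::mutate(summary = sprintf("%.4f +/- %.4f", .data$boot_mean, .data$half_width)) |>
    dplyr::select("depth", "metric", "estimate", "summary")
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' Metrics as a plain tibble
#' @param x An `ec_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ec_metrics
#' @export
tidy.ec_metrics <- function(x, ...) tibble::as_tibble(x)

#' One-row metrics summary
#' @param x An `ec_metrics` object.
#' @param ... Unused.
#' @return One-row tibble with evaluation set-up.
#' @method glance ec_metrics
#' @export
glance.ec_metrics <- function(x, ...) {
  tibble::tibble(n_test = attr(x, "n_test"),
                 n_resamples = attr(x, "n_resamples"),
                 level = attr(x, "level"),
                 seed = attr(x, "seed"))
}

#' Write a metrics report as JSON
#'
#' Per-depth blocks, each metric as `{estimate, boot_mean, half_width,
#' ci_lower, ci_upper}`, plus the evaluation set-up.
#'
#' @param metrics An `ec_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  stopifnot(inherits(metrics, "ec_metrics"))
  df <- tibble::as_tibble(metrics)
  per_depth <- lapply(split(df, df$depth), function(block) {
    vals <- lapply(seq_len(nrow(block)), function(i) {
      as.list(block[i, c("estimate", "boot_mean", "half_width",
                         "ci_lower", "ci_upper")])
    })
    names(vals) <- block$metric
    vals
  })
  payload <- list(
    n_test = attr(metrics, "n_test"),
    n_resamples = attr(metrics, "n_resamples"),
    level = attr(metrics, "level"),
    seed = attr(metrics, "seed"),
    depths = per_depth
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write predictions as TSV
#' @param predictions Tibble from [predict_nn()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(predictions[, c("query", "predicted_ec", "neighbor", "similarity")],
                   path)
  invisible(path)
}
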