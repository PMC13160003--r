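#' Construct the unseen-EC4 train/test split
#'
#' Groups cleaned records by full EC number (EC4) and builds a split in which
#' no EC4 label is shared between train and test, while every EC3 family seen
#' in test is represented in training. Within each EC3 family the largest EC4
#' group is treated as the established class and moved to training; the
#' remaining EC4 groups, sorted by ascending size, are appended whole to the
#' test-candidate set until its size first reaches `ceiling(test_fraction * N)`
#' (so the final group may overshoot the target); everything else goes to
#' training. Ties in group size are broken by lexicographic order of the
#' canonical EC string, making the construction fully deterministic.
#'
#' This emulates the realistic head--tail regime: newly emerging EC4 classes
#' tend to be small, so the test set is enriched for rare labels whose EC3
#' family is nonetheless known.
#'
#' @param records A cleaned record tibble with columns `entry` and `ec`
#'   (canonical four-field EC strings).
#' @param test_fraction Target test proportion, in (0, 1).
#' @return An object of class `ec_split` with tibbles `train` and `test`,
#'   `mode = "unseen"`, and `provenance` (one row per EC4 group: `ec`, `size`,
#'   `assigned`, `reason`).
#' @export
build_unseen_split <- function(records, test_fraction = 0.2) {
  records <- tibble::as_tibble(records)
  if (length(test_fraction) != 1L || !is.finite(test_fraction) ||
      test_fraction <= 0 || test_fraction >= 1) {
    rlang::abort("`test_fraction` must be a single number in (0, 1).")
  }
  n <- nrow(records)
  groups <- records |>
    dplyr::count(.data$ec, name = "size") |>
    dplyr::mutate(ec3 = ec_prefix(.data$ec, 3L))

  # Largest EC4 group per EC3 family -> train (tie: lexicographically first EC).
  groups <- groups |> dplyr::arrange(dplyr::desc(.data$size), .data$ec)
  head_ecs <- groups |>
    dplyr::group_by(.data$ec3) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$ec)

  rest <- groups |>
    dplyr::filter(!.data$ec %in% head_ecs) |>
    dplyr::arrange(.data$size, .data$ec)

  target <- ceiling(test_fraction * n)
  cum <- cumsum(rest$size)
  n_test_groups <- if (nrow(rest) == 0L) 0L else {
    hit <- which(cum >= target)
    if (length(hit) == 0L) nrow(rest) else hit[1L]
  }
  test_ecs <- rest$ec[seq_len(n_test_groups)]

  provenance <- groups |>
    dplyr::arrange(.data$ec) |>
    dplyr::mutate(
      assigned = dplyr::if_else(.data$ec %in% test_ecs, "test", "train"),
      reason = dplyr::case_when(
        .data$ec %in% head_ecs ~ "largest_in_ec3_family",
        .data$ec %in% test_ecs ~ "ascending_fill_to_target",
        TRUE ~ "remainder_to_train"
      )
    ) |>
    dplyr::select("ec", "size", "assigned", "reason")

  new_ec_split(
    train = records |> dplyr::filter(!.data$ec %in% test_ecs),
    test = records |> dplyr::filter(.data$ec %in% test_ecs),
    mode = "unseen",
    provenance = provenance
  )
}

#' Construct the seen (random, in-distribution) train/test split
#'
#' Samples `ceiling(test_fraction * N)` records uniformly at random (seeded) as
#' test candidates, then retains only candidates whose EC4 label still occurs
#' in the remaining training pool, so the test label space is contained in the
#' training label space.
#'
#' @param records Cleaned record tibble with `entry` and `ec` columns.
#' @param test_fraction Target test proportion, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the split exactly.
#' @return An `ec_split` object with `mode = "seen"`; `provenance` records per
#'   candidate whether it was retained or dropped for a vanished label.
#' @export
build_seen_split <- function(records, test_fraction = 0.2, seed = 1L) {
  records <- tibble::as_tibble(records)
  if (length(test_fraction) != 1L || !is.finite(test_fraction) ||
      test_fraction <= 0 || test_fraction >= 1) {
    rlang::abort("`test_fraction` must be a single number in (0, 1).")
  }
  n <- nrow(records)
  n_cand <- min(n, ceiling(test_fraction * n))
  cand_idx <- withr::with_seed(seed, sample.int(n, n_cand))
  train <- records[-cand_idx, , drop = FALSE]
  cand <- records[cand_idx, , drop = FALSE]
  retained <- cand$ec %in% unique(train$ec)
  provenance <- tibble::tibble(
    entry = cand$entry, ec = cand$ec,
    assigned = dplyr::if_else(retained, "test", "dropped"),
    reason = dplyr::if_else(retained, "label_in_train", "label_absent_from_train")
  )
  new_ec_split(
    train = tibble::as_tibble(train),
    test = tibble::as_tibble(cand[retained, , drop = FALSE]),
    mode = "seen",
    provenance = provenance
  )
}

new_ec_split <- function(train, test, mode, provenance) {
  out <- list(train = train, test = test, mode = mode, provenance = provenance)
  class(out) <- "ec_split"
  out
}

#' @export
print.ec_split <- function(x, ...) {
  cat(sprintf("EC %s split: %d train / %d test records (%d / %d unique EC4)\n",
              x$mode, nrow(x$train), nrow(x$test),
              length(unique(x$train$ec)), length(unique(x$test$ec))))
  invisible(x)
}

#' Per-group (or per-candidate) assignment table of a split
#' @param x An `ec_split` object.
#' @param ... Unused.
#' @return The provenance tibble.
#' @method tidy ec_split
#' @export
tidy.ec_split <- function(x, ...) x$provenance

#' One-row summary of a split
#' @param x An `ec_split` object.
#' @param ... Unused.
#' @return A one-row tibble with sizes and unique-label counts.
#' @method glance ec_split
#' @export
glance.ec_split <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_train = nrow(x$train), n_test = nrow(x$test),
    n_ec_train = length(unique(x$train$ec)),
    n_ec_test = length(unique(x$test$ec))
  )
}

#' Remove test records with close training homologs
#'
#' Applies identity/coverage filtering against an alignment hit table (BLAST
#' tabular orientation: test record as query, training sequence as subject). A
#' test record is removed when any of its query-side hits has percent identity
#' at or above `identity_threshold` *and* alignment coverage at or above
#' `coverage_threshold` of either the full query or the full subject sequence
#' length. Records with no qualifying hit (including records with no hits at
#' all) are kept. Hits in which a test entry appears only as subject are
#' ignored.
#'
#' @param test Tibble of test records (`entry`, `ec`, ...).
#' @param hits Tibble of hits with columns `qseqid`, `sseqid`, `pident`
#'   (percent, 0-100) and `length` (aligned residues, gaps included).
#' @param lengths Named integer vector: full sequence length per entry id, for
#'   every id appearing in `hits`.
#' @param identity_threshold Percent identity threshold (e.g. 50, 30, 10).
#' @param coverage_threshold Coverage fraction threshold (default 0.8).
#' @return The surviving test records, a tibble. Lower identity thresholds
#'   remove supersets, so surviving sets are nested across thresholds.
#' @export
filter_by_similarity <- function(test, hits, lengths, identity_threshold,
                                 coverage_threshold = 0.8) {
  test <- tibble::as_tibble(test)
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0L) return(test)
  ids <- unique(c(hits$qseqid, hits$sseqid))
  missing <- setdiff(ids, names(lengths))
  if (length(missing) > 0L) {
    rlang::abort(paste0("No sequence length for id(s): ",
                        paste(utils::head(missing, 5L), collapse = ", ")))
  }
  qlen <- unname(lengths[hits$qseqid])
  slen <- unname(lengths[hits$sseqid])
  cov_q <- hits$length / qlen
  cov_s <- hits$length / slen
  offending <- hits$pident >= identity_threshold &
    (cov_q >= coverage_threshold | cov_s >= coverage_threshold)
  remove_ids <- unique(hits$qseqid[offending])
  test |> dplyr::filter(!.data$entry %in% remove_ids)
}

#' Keep only experimentally supported test records
#'
#' Retains records whose `evidence_experimental` flag is `TRUE`; a missing
#' column or `NA` flag is treated as lack of experimental support. This mirrors
#' restricting evaluation to annotations backed by experimental evidence
#' metadata rather than computational propagation.
#'
#' @param test Tibble of records, optionally with a logical
#'   `evidence_experimental` column.
#' @return The experimentally supported subset, a tibble.
#' @export
filter_experimental <- function(test) {
  test <- tibble::as_tibble(test)
  if (!"evidence_experimental" %in% names(test)) {
    return(test[0, , drop = FALSE])
  }
  flag <- test$evidence_experimental
  flag[is.na(flag)] <- FALSE
  test[flag, , drop = FALSE]
}

#' Label-frequency statistics of a record set
#'
#' @param records Tibble with canonical `ec` column.
#' @return A list of class `ec_stats`: `per_ec4` (tibble `ec`, `n`), `per_ec1`
#'   (tibble `ec1`, `n`), `n_records`, `n_unique_ec4`.
#' @export
compute_dataset_stats <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    out <- list(per_ec4 = tibble::tibble(ec = character(), n = integer()),
                per_ec1 = tibble::tibble(ec1 = character(), n = integer()),
                n_records = 0L, n_unique_ec4 = 0L)
    class(out) <- "ec_stats"
    return(out)
  }
  per_ec4 <- records |> dplyr::count(.data$ec, name = "n")
  per_ec1 <- records |>
    dplyr::mutate(ec1 = ec_prefix(.data$ec, 1L)) |>
    dplyr::count(.data$ec1, name = "n")
  out <- list(per_ec4 = per_ec4, per_ec1 = per_ec1,
              n_records = nrow(records), n_unique_ec4 = nrow(per_ec4))
  class(out) <- "ec_stats"
  out
}

#' @export
print.ec_stats <- function(x, ...) {
  cat(sprintf("%d records, %d unique EC4 labels, %d EC classes\n",
              x$n_records, x$n_unique_ec4, nrow(x$per_ec1)))
  invisible(x)
}

#' Write a split manifest as TSV
#'
#' Writes one row per record with columns `entry`, `ec`, `split`.
#'
#' @param split An `ec_split` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "ec_split"))
  manifest <- dplyr::bind_rows(
    split$train |> dplyr::select("entry", "ec") |> dplyr::mutate(split = "train"),
    split$test |> dplyr::select("entry", "ec") |> dplyr::mutate(split = "test")
  )
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' Write dataset statistics as JSON
#'
#' @param stats An `ec_stats` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dataset_stats <- function(stats, path) {
  stopifnot(inherits(stats, "ec_stats"))
  jsonlite::write_json(
    list(n_records = stats$n_records, n_unique_ec4 = stats$n_unique_ec4,
         per_ec1 = stats$per_ec1, per_ec4 = stats$per_ec4),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
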