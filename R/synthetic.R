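#' Specification of a synthetic hierarchical enzyme dataset
#'
#' Describes a fully synthetic EC-annotated dataset whose embeddings carry a
#' planted four-level hierarchical cluster structure: every EC4 class mean is
#' a sum of per-level Gaussian offsets with decreasing scales
#' `sigma[1] > sigma[2] > sigma[3] > sigma[4]`, so proteins sharing a deeper
#' prefix are closer in expectation. Within-class noise `sigma_noise` and
#' pure-noise nuisance dimensions blur the structure, emulating the fact that
#' general-purpose protein embeddings carry much variance unrelated to
#' catalytic function. Per EC3 family one EC4 class is pinned to the top of
#' the size range (the established head class) while the rest draw smaller
#' sizes, reproducing the head--tail imbalance that the unseen-EC4 split
#' construction relies on.
#'
#' @param n_ec1,n_ec2,n_ec3,n_ec4 Fan-out per level: number of EC1 classes,
#'   EC2 per EC1, EC3 per EC2, EC4 per EC3. Defaults 3, 2, 2, 3.
#' @param size_range Length-2 integer range of proteins per EC4 class,
#'   default `c(6, 20)`; the head class of each EC3 family gets the maximum.
#' @param dim Total embedding dimension `d`, default 32.
#' @param nuisance_dims Trailing dimensions carrying pure noise (no class
#'   signal), default `dim / 2`.
#' @param sigma Length-4 decreasing positive scales of the per-level mean
#'   offsets, default `c(1, 0.5, 0.3, 0.15)`.
#' @param sigma_noise Within-class (and nuisance) noise scale, default 0.45.
#' @param seq_length_range Length-2 range of sequence lengths, default
#'   `c(50, 120)`.
#' @param seed Integer seed; the whole dataset is a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_ec1 = 3L, n_ec2 = 2L, n_ec3 = 2L, n_ec4 = 3L,
                           size_range = c(6L, 20L), dim = 32L,
                           nuisance_dims = NULL, sigma = c(1, 0.5, 0.3, 0.15),
                           sigma_noise = 0.45, seq_length_range = c(50L, 120L),
                           seed = 1L) {
  if (is.null(nuisance_dims)) nuisance_dims <- as.integer(dim / 2)
  stopifnot(n_ec1 >= 1L, n_ec2 >= 1L, n_ec3 >= 1L, n_ec4 >= 1L,
            length(size_range) == 2L, size_range[1] >= 1L,
            size_range[2] >= size_range[1],
            dim >= 2L, nuisance_dims >= 0L, nuisance_dims < dim,
            length(sigma) == 4L, all(diff(sigma) < 0), all(sigma > 0),
            sigma_noise > 0, length(seq_length_range) == 2L,
            seq_length_range[1] >= 1L)
  structure(list(n_ec1 = as.integer(n_ec1), n_ec2 = as.integer(n_ec2),
                 n_ec3 = as.integer(n_ec3), n_ec4 = as.integer(n_ec4),
                 size_range = as.integer(size_range), dim = as.integer(dim),
                 nuisance_dims = as.integer(nuisance_dims), sigma = sigma,
                 sigma_noise = sigma_noise,
                 seq_length_range = as.integer(seq_length_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a synthetic hierarchical dataset
#'
#' Materializes a [synthetic_spec()] into protein records (entry id, valid EC4
#' label, random amino-acid sequence), unit-normalized base embeddings with
#' the planted hierarchical structure, and the ground-truth class means.
#' Synthetic EC fields use small integers starting at 1 and never 99.
#'
#' @param spec A `synthetic_spec`.
#' @return A list of class `synthetic_dataset`: `records` (tibble `entry`,
#'   `ec`, `sequence`), `embeddings` (matrix, rownames = entry), `class_means`
#'   (matrix, rownames = EC4 labels, signal dimensions only are non-zero in
#'   expectation), `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    d_sig <- spec$dim - spec$nuisance_dims
    ec4_labels <- character(0)
    means <- list()
    sizes <- integer(0)
    for (i1 in seq_len(spec$n_ec1)) {
      m1 <- stats::rnorm(d_sig, sd = spec$sigma[1])
      for (i2 in seq_len(spec$n_ec2)) {
        m2 <- m1 + stats::rnorm(d_sig, sd = spec$sigma[2])
        for (i3 in seq_len(spec$n_ec3)) {
          m3 <- m2 + stats::rnorm(d_sig, sd = spec$sigma[3])
          for (i4 in seq_len(spec$n_ec4)) {
            lab <- paste(i1, i2, i3, i4, sep = ".")
            ec4_labels <- c(ec4_labels, lab)
            means[[lab]] <- m3 + stats::rnorm(d_sig, sd = spec$sigma[4])
            # head class (first serial) pinned to the top of the size range
            sizes <- c(sizes, if (i4 == 1L) spec$size_range[2] else {
              if (spec$size_range[2] - 1L >= spec$size_range[1]) {
                sample(spec$size_range[1]:(spec$size_range[2] - 1L), 1L)
              } else spec$size_range[1]
            })
          }
        }
      }
    }
    class_means <- do.call(rbind, means)
    rownames(class_means) <- ec4_labels

    n <- sum(sizes)
    ec <- rep(ec4_labels, sizes)
    entry <- sprintf("SYN%05d", seq_len(n))
    emb <- matrix(0, n, spec$dim)
    emb[, seq_len(d_sig)] <- class_means[ec, , drop = FALSE] +
      matrix(stats::rnorm(n * d_sig, sd = spec$sigma_noise), n, d_sig)
    if (spec$nuisance_dims > 0L) {
      emb[, (d_sig + 1L):spec$dim] <-
        matrix(stats::rnorm(n * spec$nuisance_dims, sd = spec$sigma_noise),
               n, spec$nuisance_dims)
    }
    emb <- emb / sqrt(rowSums(emb^2))
    rownames(emb) <- entry

    seq_lens <- sample(spec$seq_length_range[1]:spec$seq_length_range[2], n,
                       replace = TRUE)
    sequences <- vapply(seq_lens, function(L) {
      paste(sample(AMINO_ACIDS, L, replace = TRUE), collapse = "")
    }, character(1))

    structure(list(
      records = tibble::tibble(entry = entry, ec = ec, sequence = sequences),
      embeddings = emb,
      class_means = class_means,
      spec = spec
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d proteins, %d EC4 classes (%dx%dx%dx%d hierarchy), dim %d (%d nuisance)\n",
              nrow(x$records), nrow(x$class_means), x$spec$n_ec1, x$spec$n_ec2,
              x$spec$n_ec3, x$spec$n_ec4, x$spec$dim, x$spec$nuisance_dims))
  invisible(x)
}

# Deterministic small integer seed from an arbitrary string.
string_seed <- function(s, base_seed = 0L) {
  v <- utf8ToInt(s)
  h <- base_seed %% 2147483647
  for (ch in v) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Embedding provider over a synthetic dataset
#'
#' Implements the provider contract for desk-scale runs: `base_embedding(id)`
#' returns the stored vector; `embed_sequence(seq)` returns the owning
#' record's vector exactly for an original sequence, and for a mask-augmented
#' variant (one residue replaced by `"*"`) returns the owner's vector plus a
#' small deterministic perturbation (pre-normalization norm <= 0.05, seeded
#' from the sequence text), then unit-normalized — so a masked view is a
#' near-duplicate positive with cosine >= 0.99 to the original.
#'
#' @param dataset A `synthetic_dataset`.
#' @return An [embedding_provider()].
#' @export
synthetic_provider <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  emb <- dataset$embeddings
  seq_to_entry <- stats::setNames(dataset$records$entry, dataset$records$sequence)
  seqs <- dataset$records$sequence
  base_seed <- dataset$spec$seed

  find_owner <- function(sequence) {
    hit <- seq_to_entry[sequence]
    if (!is.na(hit)) return(list(entry = unname(hit), masked = FALSE))
    # masked variant: same length, equal at all non-"*" positions
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    star <- chars == "*"
    if (any(star)) {
      cand_len <- nchar(seqs) == length(chars)
      for (i in which(cand_len)) {
        oc <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        if (all(oc[!star] == chars[!star])) {
          return(list(entry = dataset$records$entry[i], masked = TRUE))
        }
      }
    }
    rlang::abort("Unknown sequence: no synthetic record matches.")
  }

  embedding_provider(
    base_embedding = function(entry) {
      if (!entry %in% rownames(emb)) {
        rlang::abort(sprintf("Unknown entry id %s.", entry))
      }
      emb[entry, ]
    },
    embed_sequence = function(sequence) {
      owner <- find_owner(sequence)
      v <- emb[owner$entry, ]
      if (!owner$masked) return(v)
      pert <- withr::with_seed(string_seed(sequence, base_seed), {
        stats::rnorm(length(v))
      })
      pert <- 0.05 * pert / sqrt(sum(pert^2))
      out <- v + pert
      out / sqrt(sum(out^2))
    }
  )
}

#' Generate a synthetic alignment hit table
#'
#' Emits BLAST-tabular-style hits (query = candidate test record, subject =
#' training record) whose percent identity correlates with base-embedding
#' cosine similarity plus noise, spanning the 10/30/50% threshold regimes,
#' with alignment lengths between half and full query length so both coverage
#' outcomes occur.
#'
#' @param query_records Tibble of query-side records (`entry`, `sequence`).
#' @param subject_records Tibble of subject-side records.
#' @param dataset The `synthetic_dataset` providing embeddings.
#' @param hits_per_query Number of subject hits sampled per query, default 5.
#' @param seed Integer seed.
#' @return A tibble with columns `qseqid`, `sseqid`, `pident`, `length`.
#' @export
generate_hit_table <- function(query_records, subject_records, dataset,
                               hits_per_query = 5L, seed = 1L) {
  query_records <- tibble::as_tibble(query_records)
  subject_records <- tibble::as_tibble(subject_records)
  if (nrow(query_records) == 0L || nrow(subject_records) == 0L) {
    return(tibble::tibble(qseqid = character(), sseqid = character(),
                          pident = numeric(), length = integer()))
  }
  emb <- dataset$embeddings
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(query_records)), function(i) {
      q <- query_records$entry[i]
      nsub <- min(hits_per_query, nrow(subject_records))
      subs <- subject_records$entry[sample.int(nrow(subject_records), nsub)]
      cosine <- as.numeric(emb[subs, , drop = FALSE] %*% emb[q, ])
      pident <- pmin(98, pmax(2, 35 + 45 * cosine + stats::rnorm(nsub, sd = 12)))
      qlen <- nchar(query_records$sequence[i])
      alnlen <- pmax(1L, as.integer(round(stats::runif(nsub, 0.5, 1) * qlen)))
      tibble::tibble(qseqid = q, sseqid = subs, pident = pident, length = alnlen)
    })
    dplyr::bind_rows(rows)
  })
}

#' Write all synthetic fixtures to a directory
#'
#' Writes FASTA sequences, the label table, the embedding table, a hit table
#' (test candidates vs training records under an unseen split at the default
#' fraction) and a ground-truth JSON (class means and spec) into `dir`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the hit table.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dataset, dir, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    labels = file.path(dir, "labels.tsv"),
    embeddings = file.path(dir, "embeddings.tsv"),
    hits = file.path(dir, "hits.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(stats::setNames(dataset$records$sequence, dataset$records$entry),
              paths["fasta"])
  readr::write_tsv(dataset$records[, c("entry", "ec", "sequence")], paths["labels"])
  write_embeddings(dataset$embeddings, paths["embeddings"])
  split <- build_unseen_split(dataset$records)
  hits <- generate_hit_table(split$test, split$train, dataset, seed = seed)
  readr::write_tsv(hits, paths["hits"], col_names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(dataset$spec),
         class_means = apply(dataset$class_means, 1L, identity, simplify = FALSE)),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
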