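#' Read a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased and line wraps joined.
#'
#' @param path FASTA file path.
#' @return Named character vector (id -> sequence); empty for an empty file.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("Duplicate FASTA id(s): ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector (id -> sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an EC label table
#'
#' Reads a TSV with required columns `entry` and `ec` (and optional
#' `sequence`); when `fasta` is given, sequences are joined on `entry`. ECs
#' are validated with [ec_parse()]: rows with malformed ECs are reported in a
#' `rejects` tibble carrying their line numbers and rejection reasons, never
#' silently dropped.
#'
#' @param path Label TSV path.
#' @param fasta Optional FASTA path supplying sequences.
#' @return A list: `records` (tibble `entry`, `ec` canonical, `sequence` if
#'   available, plus any extra columns), `rejects` (tibble `line`, `entry`,
#'   `ec`, `reason`).
#' @export
read_label_table <- function(path, fasta = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (col in c("entry", "ec")) {
    if (!col %in% names(tab)) {
      rlang::abort(sprintf("Label table is missing required column `%s`.", col))
    }
  }
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    tab$sequence <- unname(seqs[tab$entry])
  }
  parsed <- ec_parse(tab$ec)
  bad <- !is.na(parsed$rejection)
  rejects <- tibble::tibble(
    line = which(bad) + 1L, # +1 for the header line
    entry = tab$entry[bad],
    ec = tab$ec[bad],
    reason = parsed$rejection[bad]
  )
  records <- tab[!bad, , drop = FALSE]
  records$ec <- parsed$ec[!bad]
  list(records = tibble::as_tibble(records), rejects = rejects)
}

#' Read an embedding table
#'
#' TSV with the entry id in the first column and `d` decimal float columns;
#' all rows must have the same width.
#'
#' @param path Embedding TSV path (with header).
#' @return Numeric matrix with rownames = entry ids.
#' @export
read_embeddings <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0L) {
    rlang::abort(sprintf("Malformed embedding table at line %d: %s.",
                         probs$row[1L] + 1L, probs$expected[1L]))
  }
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("Duplicate entry id(s) in embedding table: ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  # parse through base R, which rounds decimal literals correctly to the ulp
  cols <- lapply(tab[-1L], function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v) && !all(is.na(x))) {
      rlang::abort(sprintf("Non-numeric embedding value at line %d.",
                           which(is.na(v) & !is.na(x))[1L] + 1L))
    }
    v
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(ids, NULL)
  m
}

#' Write an embedding table
#'
#' Values are written at 17 significant digits so a read/write round trip is
#' exact to double precision.
#'
#' @param embeddings Numeric matrix, rownames = entry ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  df <- as.data.frame(apply(embeddings, 2L, function(x) sprintf("%.17g", x)))
  names(df) <- paste0("v", seq_len(ncol(embeddings)))
  df <- cbind(entry = rownames(embeddings), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}

#' Read a BLAST-tabular hit table
#'
#' Consumes the first four columns of an outfmt-6-style TSV (`qseqid`,
#' `sseqid`, `pident`, `length`); any further columns are ignored. The file
#' has no header.
#'
#' @param path Hit table path.
#' @return Tibble with columns `qseqid`, `sseqid`, `pident` (percent),
#'   `length` (integer).
#' @export
read_hit_table <- function(path) {
  if (file.size(path) == 0L) {
    return(tibble::tibble(qseqid = character(), sseqid = character(),
                          pident = numeric(), length = integer()))
  }
  # rows may have ragged trailing columns (only the first four are consumed)
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  )
  if (ncol(raw) < 4L) rlang::abort("Hit table needs at least 4 columns (qseqid, sseqid, pident, length).")
  pident <- suppressWarnings(as.numeric(raw[[3L]]))
  len <- suppressWarnings(as.integer(raw[[4L]]))
  bad <- which(is.na(pident) | is.na(len))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("Non-numeric pident/length in hit table at line %d.", bad[1L]))
  }
  tibble::tibble(qseqid = raw[[1L]], sseqid = raw[[2L]], pident = pident,
                 length = len)
}

#' Mean within-EC3 minus between-EC1 similarity
#'
#' A scalar summary of how hierarchy-consistent an embedding space is: the
#' mean cosine similarity over protein pairs sharing an EC3 family minus the
#' mean over pairs with different EC1 classes. Contrastive training that
#' respects the hierarchy should increase this gap.
#'
#' @param embeddings Numeric matrix of unit rows.
#' @param labels Canonical EC4 strings aligned with rows.
#' @return Scalar gap (within-EC3 mean similarity minus between-EC1 mean).
#' @export
hierarchy_similarity_gap <- function(embeddings, labels) {
  stopifnot(is.matrix(embeddings), nrow(embeddings) == length(labels))
  sims <- tcrossprod(embeddings)
  ec3 <- ec_prefix(labels, 3L)
  ec1 <- ec_prefix(labels, 1L)
  same3 <- outer(ec3, ec3, "==")
  diff1 <- outer(ec1, ec1, "!=")
  off <- !diag(TRUE, length(labels))
  mean(sims[same3 & off]) - mean(sims[diff1])
}
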