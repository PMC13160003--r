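#' Parse and validate EC numbers
#'
#' Normalizes raw EC annotation text (stripping an optional `"EC"` prefix and
#' surrounding whitespace) and validates it against the four-field EC format.
#' A valid EC number has exactly four dot-separated positive integer fields,
#' none of which equals 99 (the "other" catch-all serial, excluded because it
#' does not denote a concrete enzymatic activity).
#'
#' Rejections are values, not errors: each input is classified as valid or
#' tagged with one of three rejection reasons, so malformed annotations can be
#' reported rather than silently dropped.
#'
#' @param raw Character vector of raw EC annotation strings.
#' @return A tibble with one row per input: `raw` (the input), `ec` (canonical
#'   dotted form, `NA` if rejected), `ec1`..`ec4` (integer fields, `NA` if
#'   rejected) and `rejection` (`NA` for valid labels, otherwise one of
#'   `"incomplete"` (fewer than four fields), `"invalid"` (a non-digit field
#'   after normalization) or `"forbidden_99"` (a field equal to 99)).
#' @examples
#' ec_parse(c("2.1.3.4", " EC 3.4.21.1 ", "1.2.99.5", "2.3.1", "1.a.3.4"))
#' @export
ec_parse <- function(raw) {
  raw <- as.character(raw)
  norm <- stringr::str_trim(raw)
  norm <- stringr::str_remove(norm, stringr::regex("^EC[:\\s]*", ignore_case = TRUE))
  norm <- stringr::str_trim(norm)

  parts <- stringr::str_split(norm, stringr::fixed("."))
  parsed <- purrr::map(parts, function(p) {
    if (length(p) < 4L) {
      return(list(fields = rep(NA_integer_, 4L), rejection = "incomplete"))
    }
    f <- suppressWarnings(as.integer(p))
    if (length(p) > 4L || !all(stringr::str_detect(p, "^[0-9]+$")) ||
        anyNA(f) || any(f < 1L)) {
      return(list(fields = rep(NA_integer_, 4L), rejection = "invalid"))
    }
    if (any(f == 99L)) {
      return(list(fields = rep(NA_integer_, 4L), rejection = "forbidden_99"))
    }
    list(fields = f, rejection = NA_character_)
  })

  fields <- do.call(rbind, purrr::map(parsed, "fields"))
  rejection <- purrr::map_chr(parsed, "rejection")
  ec <- ifelse(is.na(rejection),
               paste(fields[, 1L], fields[, 2L], fields[, 3L], fields[, 4L], sep = "."),
               NA_character_)
  tibble::tibble(
    raw = raw, ec = ec,
    ec1 = fields[, 1L], ec2 = fields[, 2L], ec3 = fields[, 3L], ec4 = fields[, 4L],
    rejection = rejection
  )
}

#' EC prefix at a hierarchy depth
#'
#' Returns the first `depth` fields of canonical EC strings as a dotted
#' identifier: depth 1 is the EC class (e.g. `"2"`), depth 3 the EC3 family
#' (e.g. `"2.1.3"`) and depth 4 the full label.
#'
#' @param ec Character vector of canonical EC strings (`"c.s.ss.n"`).
#' @param depth Integer in 1..4.
#' @return Character vector of depth-`depth` prefixes.
#' @examples
#' ec_prefix("2.1.3.4", 3) # "2.1.3"
#' @export
ec_prefix <- function(ec, depth) {
  if (length(depth) != 1L || !depth %in% 1:4) {
    rlang::abort("`depth` must be a single integer in 1..4.")
  }
  if (depth == 4L) return(as.character(ec))
  purrr::map_chr(stringr::str_split(ec, stringr::fixed(".")), function(p) {
    paste(p[seq_len(depth)], collapse = ".")
  })
}

#' Clean an EC-annotated protein record table
#'
#' Applies the deterministic three-rule cleaning pipeline, in order:
#'
#' 1. **Multifunction removal** — every record of an entry associated with two
#'    or more distinct EC strings (valid or not) is removed, whether the ECs
#'    are listed in one field (separated by `;` or `,`) or spread over several
#'    records; a protein with several annotated activities has no single
#'    ground-truth label.
#' 2. **Invalid-EC removal** — records whose EC fails [ec_parse()] (incomplete,
#'    non-digit, or containing a 99 field) are removed.
#' 3. **Deduplication** — among records sharing an identical (canonical EC,
#'    sequence) pair, only the first in input order is kept.
#'
#' Each record receives exactly one disposition: `kept` or the first rule that
#' removed it, so disposition counts always sum to the input size and cleaning
#' is idempotent.
#'
#' @param records A data frame with columns `entry`, `ec` (raw EC text) and
#'   optionally `sequence` (required for rule 3 to distinguish sequences; if
#'   absent, deduplication uses the EC alone within an entry's records).
#' @return An object of class `ec_cleaning`: a list with
#'   * `records`: tibble of kept records with canonical `ec` plus any other
#'     input columns;
#'   * `report`: named list of counts (`kept`, `removed_multifunction`,
#'     `removed_invalid`, `removed_duplicate`, `input`);
#'   * `dispositions`: tibble with one row per input record (`entry`, `raw_ec`,
#'     `disposition`).
#' @seealso [tidy.ec_cleaning()], [glance.ec_cleaning()]
#' @export
clean_records <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("entry", "ec") %in% names(records)))
  n <- nrow(records)
  if (n == 0L) {
    out <- list(
      records = records,
      report = list(kept = 0L, removed_multifunction = 0L, removed_invalid = 0L,
                    removed_duplicate = 0L, input = 0L),
      dispositions = tibble::tibble(entry = character(), raw_ec = character(),
                                    disposition = character())
    )
    class(out) <- "ec_cleaning"
    return(out)
  }

  parsed <- ec_parse(records$ec)
  disposition <- rep(NA_character_, n)

  # Rule 1: entries associated with >= 2 distinct EC strings, whether listed
  # in one field (";"/"," separated) or across several records; comparison is
  # on trimmed raw text, so one valid plus one malformed annotation still
  # counts as two.
  ec_lists <- purrr::map(stringr::str_split(records$ec, "[;,]"),
                         function(x) unique(stringr::str_trim(x[stringr::str_trim(x) != ""])))
  per_entry <- tapply(ec_lists, records$entry,
                      function(l) length(unique(unlist(l))))
  multi_entries <- names(per_entry)[per_entry >= 2L]
  disposition[records$entry %in% multi_entries] <- "removed_multifunction"

  # Rule 2: invalid EC after normalization.
  idx <- is.na(disposition) & !is.na(parsed$rejection)
  disposition[idx] <- "removed_invalid"

  # Rule 3: duplicate (canonical EC, sequence) pairs; first in input order wins.
  remaining <- which(is.na(disposition))
  seqs <- if ("sequence" %in% names(records)) records$sequence else ""
  key <- paste(parsed$ec[remaining], seqs[remaining], sep = "\r")
  dup <- duplicated(key)
  disposition[remaining[dup]] <- "removed_duplicate"
  disposition[is.na(disposition)] <- "kept"

  kept_idx <- which(disposition == "kept")
  kept <- records[kept_idx, , drop = FALSE]
  kept$ec <- parsed$ec[kept_idx]

  report <- list(
    kept = length(kept_idx),
    removed_multifunction = sum(disposition == "removed_multifunction"),
    removed_invalid = sum(disposition == "removed_invalid"),
    removed_duplicate = sum(disposition == "removed_duplicate"),
    input = n
  )
  out <- list(
    records = tibble::as_tibble(kept),
    report = report,
    dispositions = tibble::tibble(entry = records$entry, raw_ec = records$ec,
                                  disposition = disposition)
  )
  class(out) <- "ec_cleaning"
  out
}

#' @export
print.ec_cleaning <- function(x, ...) {
  r <- x$report
  cat("EC cleaning:", r$input, "records ->", r$kept, "kept\n")
  cat("  removed: multifunction", r$removed_multifunction,
      "| invalid EC", r$removed_invalid,
      "| duplicate (EC, sequence)", r$removed_duplicate, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-record dispositions of a cleaning run
#'
#' @param x An `ec_cleaning` object.
#' @param ... Unused.
#' @return A tibble with one row per input record.
#' @method tidy ec_cleaning
#' @export
tidy.ec_cleaning <- function(x, ...) x$dispositions

#' One-row summary of a cleaning run
#'
#' @param x An `ec_cleaning` object.
#' @param ... Unused.
#' @return A one-row tibble of disposition counts.
#' @method glance ec_cleaning
#' @export
glance.ec_cleaning <- function(x, ...) tibble::as_tibble(x$report)

#' Serialize a cleaning report to JSON
#'
#' @param x An `ec_cleaning` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(x, path) {
  stopifnot(inherits(x, "ec_cleaning"))
  jsonlite::write_json(x$report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
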