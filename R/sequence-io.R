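#' Read a FASTA file into a tibble of sequence records
#'
#' One row per FASTA entry, in file order. The record id is the first
#' whitespace-delimited token of the header; residues are uppercased and must
#' come from the nucleotide alphabet `{A, C, G, T, N}`. An optional header
#' token of the form `family=<int>` (written by [generate_families()]) is
#' parsed into `truth_label` and used only for evaluation against known
#' family structure.
#'
#' @param path Path to a FASTA file. Multi-line sequences are allowed.
#' @return A tibble with columns `id` (character), `residues` (character,
#'   uppercase) and `truth_label` (integer, `NA` when no token is present).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 family=0", "ACGT", ">r2", "ggta"), fa)
#' read_fasta(fa)
#' @seealso [write_fasta()], [deduplicate()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "seqmds_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    abort(paste0("no FASTA records in ", path), class = "seqmds_parse_error")
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(
      sprintf("malformed FASTA: sequence data before any '>' header at line %d",
              nonblank[1]),
      class = "seqmds_parse_error"
    )
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  residues <- toupper(as.character(set))
  names(residues) <- NULL

  empty <- !nzchar(residues)
  if (any(empty)) {
    abort(
      paste0("empty sequence for record(s): ",
             paste(ids[empty], collapse = ", ")),
      class = "seqmds_validation_error"
    )
  }
  bad <- grepl("[^ACGTN]", residues)
  if (any(bad)) {
    abort(
      paste0("invalid residue characters (alphabet is A/C/G/T/N) in record(s): ",
             paste(ids[bad], collapse = ", ")),
      class = "seqmds_validation_error"
    )
  }
  if (anyDuplicated(ids)) {
    abort(
      paste0("duplicated record id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      class = "seqmds_validation_error"
    )
  }
  lab <- rep(NA_integer_, length(ids))
  hit <- regmatches(headers, regexpr("family=\\d+", headers))
  has <- grepl("family=\\d+", headers)
  lab[has] <- as.integer(sub("family=", "", hit))
  tibble(id = ids, residues = residues, truth_label = lab)
}

#' Write sequence records to a FASTA file
#'
#' The inverse of [read_fasta()]: records with a non-missing `truth_label`
#' get a `family=<int>` header token so labels survive a round trip through
#' the file format.
#'
#' @param records A tibble with columns `id`, `residues` and optionally
#'   `truth_label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- validate_records(records)
  headers <- records$id
  if ("truth_label" %in% names(records)) {
    has <- !is.na(records$truth_label)
    headers[has] <- paste0(records$id[has], " family=", records$truth_label[has])
  }
  set <- Biostrings::BStringSet(setNames(records$residues, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

validate_records <- function(records, arg = "records") {
  if (!is.data.frame(records) ||
      !all(c("id", "residues") %in% names(records))) {
    abort(paste0("`", arg, "` must be a data frame with columns `id` and `residues`"),
          class = "seqmds_validation_error")
  }
  if (nrow(records) == 0) {
    abort(paste0("`", arg, "` is empty"), class = "seqmds_validation_error")
  }
  if (anyDuplicated(records$id)) {
    abort("record ids must be unique", class = "seqmds_validation_error")
  }
  if (any(!nzchar(records$residues))) {
    abort("records with empty residues are not allowed",
          class = "seqmds_validation_error")
  }
  as_tibble(records)
}

#' Remove exact duplicate sequences
#'
#' Reads that are exact full-length copies of an earlier read carry no extra
#' information for distance computation, so they are stripped before the
#' all-pairs stage; only exact residue-string matches are collapsed (no
#' prefix or substring clustering). The first occurrence is kept. The
#' mapping from each removed read to the kept read is attached so cluster
#' labels can later be propagated back to every original read.
#'
#' @param records A tibble of sequence records (see [read_fasta()]).
#' @return The unique records, with a tibble attribute `duplicate_map`
#'   (columns `duplicate_id`, `kept_id`) retrievable with [duplicate_map()].
#'   `nrow(unique) + nrow(duplicate_map)` equals `nrow(records)`.
#' @examples
#' recs <- tibble::tibble(id = c("a", "b", "c"),
#'                        residues = c("ACGT", "ACGT", "GGTA"))
#' uni <- deduplicate(recs)
#' duplicate_map(uni)
#' @export
deduplicate <- function(records) {
  records <- validate_records(records)
  first_idx <- match(records$residues, records$residues)
  is_dup <- first_idx != seq_len(nrow(records))
  map <- tibble(
    duplicate_id = records$id[is_dup],
    kept_id = records$id[first_idx[is_dup]]
  )
  out <- records[!is_dup, , drop = FALSE]
  attr(out, "duplicate_map") <- map
  out
}

#' @rdname deduplicate
#' @param unique_records The return value of [deduplicate()].
#' @export
duplicate_map <- function(unique_records) {
  attr(unique_records, "duplicate_map") %||%
    tibble(duplicate_id = character(), kept_id = character())
}

#' Split a collection into in-sample and out-of-sample index sets
#'
#' The interpolative pipeline embeds only a small in-sample subset of size M
#' by full MDS; the remaining N - M reads are placed by interpolation. The
#' split is a uniformly random partition, reproducible from `seed`. Indices
#' are 1-based positions into the (deduplicated) record collection.
#'
#' @param n_total Number of records N.
#' @param m_in_sample In-sample size M, with `1 <= M <= N`.
#' @param seed Integer RNG seed.
#' @return An object of class `sample_split`: a list with sorted integer
#'   vectors `in_sample` (length M) and `out_of_sample` (length N - M),
#'   disjoint with union `1:N`, plus the `seed` used.
#' @examples
#' split_sample(10, 4, seed = 1)
#' @export
split_sample <- function(n_total, m_in_sample, seed) {
  if (!is.numeric(n_total) || n_total < 1) {
    abort("`n_total` must be a positive count", class = "seqmds_validation_error")
  }
  if (!is.numeric(m_in_sample) || m_in_sample < 1 || m_in_sample > n_total) {
    abort("`m_in_sample` must satisfy 1 <= M <= N",
          class = "seqmds_validation_error")
  }
  in_sample <- withr::with_seed(
    seed,
    sort(sample.int(n_total, m_in_sample))
  )
  out_of_sample <- setdiff(seq_len(n_total), in_sample)
  structure(
    list(in_sample = as.integer(in_sample),
         out_of_sample = as.integer(out_of_sample),
         seed = as.integer(seed)),
    class = "sample_split"
  )
}

#' @export
print.sample_split <- function(x, ...) {
  cat("<sample_split> M =", length(x$in_sample),
      "in-sample /", length(x$out_of_sample), "out-of-sample (seed",
      paste0(x$seed, ")"), "\n")
  invisible(x)
}
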