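#' Construct a genetic distance matrix object
#'
#' A `dist_matrix` is a symmetric n x n numeric matrix of pairwise genetic
#' distances in `[0, 1]` with zero diagonal, carrying the record ids as
#' dimnames. It is the interchange object between the alignment stage, MDS
#' and k-medoids clustering.
#'
#' @param values Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @param ids Character vector of record identifiers, one per row.
#' @return A matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (ncol(values) != n || length(ids) != n) {
    abort("distance matrix must be square with one id per row",
          class = "seqmds_validation_error")
  }
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    abort("distances must be finite and in [0, 1]",
          class = "seqmds_validation_error")
  }
  if (max(abs(values - t(values))) > 1e-12 || any(diag(values) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal",
          class = "seqmds_validation_error")
  }
  dimnames(values) <- list(ids, ids)
  class(values) <- c("dist_matrix", class(values))
  values
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix>", nrow(x), "x", ncol(x), "genetic distances\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows/columns\n")
  invisible(x)
}

dm_ids <- function(delta) rownames(delta)

#' All-pairs genetic distances by Needleman-Wunsch alignment
#'
#' Aligns every unordered pair of records and fills the symmetric matrix of
#' genetic distances (see [genetic_distance()]). This is the O(N^2) stage of
#' the basic pipeline: exactly `n * (n - 1) / 2` alignments are executed and
#' counted in the ledger. Work is decomposed into blocks of pairs purely as
#' a parallelism contract — any block size and any number of workers yield
#' an identical matrix.
#'
#' @param records Tibble of sequence records (see [read_fasta()]); at least
#'   two rows.
#' @param params [alignment_params()] to use for every pair.
#' @param ledger Optional [cost_ledger()]; `nw_alignments` is incremented by
#'   `n * (n - 1) / 2`.
#' @param block_size Number of pairs per work block.
#' @param workers Number of parallel worker processes (forked; on platforms
#'   without fork the map runs sequentially).
#' @return A [dist_matrix()] with the records' ids.
#' @examples
#' recs <- generate_families(n_families = 2, members_per_family = 4, seed = 1)
#' delta <- build_distance_matrix(recs)
#' @export
build_distance_matrix <- function(records, params = alignment_params(),
                                  ledger = NULL, block_size = 5000L,
                                  workers = 1L) {
  records <- validate_records(records)
  n <- nrow(records)
  if (n < 2) {
    abort("need at least 2 records to build a distance matrix (degenerate input)",
          class = "seqmds_degenerate_error")
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ii <- pairs[, 1]; jj <- pairs[, 2]
  d <- chunked_map_numeric(
    length(ii), block_size, workers,
    function(lo, hi) {
      nw_distance_pairs_cpp(records$residues, ii[lo:hi], jj[lo:hi],
                            params$match, params$mismatch,
                            params$gap_open, params$gap_extend)
    }
  )
  ledger_add(ledger, "nw_alignments", length(ii))
  values <- matrix(0, n, n)
  values[cbind(ii, jj)] <- d
  values[cbind(jj, ii)] <- d
  dist_matrix(values, records$id)
}

# Deterministic chunked map over 1:n_items in blocks, optionally forked.
# Results are concatenated in block order, so the output never depends on
# block size or worker count.
chunked_map_numeric <- function(n_items, block_size, workers, fn) {
  block_size <- max(1L, as.integer(block_size))
  starts <- seq.int(1L, n_items, by = block_size)
  blocks <- lapply(starts, function(lo) c(lo, min(lo + block_size - 1L, n_items)))
  run <- function(b) fn(b[1], b[2])
  if (workers > 1L && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(blocks, run, mc.cores = workers,
                              mc.preschedule = TRUE)
    bad <- vapply(out, inherits, logical(1), "try-error")
    if (any(bad)) abort("parallel worker failed", class = "seqmds_parallel_error")
  } else {
    out <- lapply(blocks, run)
  }
  unlist(out, use.names = FALSE)
}

#' Write / read a distance matrix in the binary .dmat format
#'
#' A small self-describing container: 4-byte magic `DMAT`, integer version,
#' integer n, a newline-joined id block, then the n x n payload as row-major
#' 64-bit floats. The round trip is exactly lossless. Use
#' [write_distance_tsv()] for a human-readable export.
#'
#' @param m A [dist_matrix()].
#' @param path File path (conventionally `.dmat`).
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the [dist_matrix()].
#' @export
write_distance_matrix <- function(m, path) {
  stopifnot(inherits(m, "dist_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("DMAT"), con)
  writeBin(c(1L, nrow(m)), con)
  id_block <- charToRaw(paste(dm_ids(m), collapse = "\n"))
  writeBin(length(id_block), con)
  writeBin(id_block, con)
  writeBin(as.numeric(t(unclass(m))), con)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "seqmds_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4 || rawToChar(magic) != "DMAT") {
    abort("not a .dmat file (bad magic)", class = "seqmds_format_error")
  }
  hdr <- readBin(con, "integer", 3)
  if (length(hdr) < 3) abort("truncated .dmat header", class = "seqmds_format_error")
  version <- hdr[1]; n <- hdr[2]; id_bytes <- hdr[3]
  if (version != 1L) {
    abort(paste0("unsupported .dmat version: ", version),
          class = "seqmds_format_error")
  }
  id_block <- readBin(con, "raw", id_bytes)
  if (length(id_block) < id_bytes) {
    abort("truncated .dmat id block", class = "seqmds_format_error")
  }
  ids <- strsplit(rawToChar(id_block), "\n", fixed = TRUE)[[1]]
  if (length(ids) != n) {
    abort(sprintf(".dmat header n (%d) disagrees with id count (%d)",
                  n, length(ids)),
          class = "seqmds_format_error")
  }
  values <- readBin(con, "numeric", n * n)
  if (length(values) < n * n) {
    abort("truncated .dmat payload", class = "seqmds_format_error")
  }
  dist_matrix(matrix(values, n, n, byrow = TRUE), ids)
}

#' Human-readable TSV export of a distance matrix
#'
#' Tab-separated values with record ids as both the header row and the
#' first column.
#'
#' @inheritParams write_distance_matrix
#' @return `path` invisibly, or the [dist_matrix()] for the reader.
#' @export
write_distance_tsv <- function(m, path) {
  stopifnot(inherits(m, "dist_matrix"))
  df <- data.frame(id = dm_ids(m), unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = c(id = "character"))
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(values), df$id)) {
    abort("TSV header ids disagree with row ids", class = "seqmds_format_error")
  }
  dist_matrix(values, df$id)
}
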