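#' Write / read the points file consumed by 3-D point-cloud viewers
#'
#' Tab-separated lines `index  x  y  z  label` with a leading `#` header
#' comment. Indices are 0-based in embedding row order (the one place the
#' package fixes a 0-based convention, for viewer compatibility);
#' coordinates carry 6 significant digits; embeddings with fewer than 3
#' dimensions are padded with a 0 z-column so downstream 3-D viewers always
#' parse.
#'
#' @param emb An [embedding()] with at most 3 dimensions.
#' @param labels Integer cluster labels aligned with the embedding rows, or
#'   `NULL` for an unlabeled export (label column 0).
#' @param path Output file path.
#' @return `write_points_file()` returns `path` invisibly;
#'   `read_points_file()` returns a tibble with columns `index`, `x`, `y`,
#'   `z`, `label`.
#' @export
write_points_file <- function(emb, labels, path) {
  coords <- as.matrix(emb)
  if (ncol(coords) > 3) {
    abort("points file format is 3-D; embed with n_dim <= 3",
          class = "seqmds_validation_error")
  }
  if (is.null(labels)) labels <- rep(0L, nrow(coords))
  if (length(labels) != nrow(coords)) {
    abort("one label per embedding row required",
          class = "seqmds_validation_error")
  }
  while (ncol(coords) < 3) coords <- cbind(coords, 0)
  lines <- "# index\tx\ty\tz\tlabel"
  if (nrow(coords) > 0) {
    lines <- c(lines, sprintf("%d\t%.6g\t%.6g\t%.6g\t%d",
                              seq_len(nrow(coords)) - 1L,
                              coords[, 1], coords[, 2], coords[, 3],
                              as.integer(labels)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_points_file
#' @export
read_points_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "seqmds_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(index = integer(), x = numeric(), y = numeric(),
                  z = numeric(), label = integer()))
  }
  df <- read.table(text = lines, sep = "\t",
                   col.names = c("index", "x", "y", "z", "label"))
  as_tibble(df)
}
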