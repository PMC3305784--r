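#' Scoring parameters for Needleman-Wunsch global alignment
#'
#' Affine-gap global alignment scoring: a match rewards `match`, a mismatch
#' costs `mismatch` (negative), and a gap of length g costs
#' `gap_open + g * gap_extend`. Defaults are EDNAFULL-like magnitudes for
#' nucleotide reads. `N` is scored as a mismatch against every base,
#' including another `N` (a conservative choice for ambiguous calls).
#'
#' @param match Integer match reward (> `mismatch`).
#' @param mismatch Integer mismatch score (typically negative).
#' @param gap_open Nonnegative integer gap-opening penalty.
#' @param gap_extend Nonnegative integer per-residue gap-extension penalty
#'   (`gap_open >= gap_extend`).
#' @return An object of class `alignment_params`.
#' @examples
#' alignment_params()
#' @export
alignment_params <- function(match = 5L, mismatch = -4L,
                             gap_open = 10L, gap_extend = 4L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= mismatch) {
    abort("`match` must exceed `mismatch`", class = "seqmds_validation_error")
  }
  if (gap_extend < 0 || gap_open < gap_extend) {
    abort("gap penalties must satisfy gap_open >= gap_extend >= 0",
          class = "seqmds_validation_error")
  }
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "alignment_params"
  )
}

#' @export
print.alignment_params <- function(x, ...) {
  cat(sprintf("<alignment_params> match %+d, mismatch %+d, gap open %d, gap extend %d\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  invisible(x)
}

#' Optimal global alignment of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment under affine-gap scoring, computed with
#' the Gotoh three-state recurrence. End gaps are penalized. The returned
#' score is the maximum over all global alignments; one optimal traceback is
#' returned under a fixed tie-break order (diagonal over vertical over
#' horizontal), which makes the identity fraction — and therefore
#' [genetic_distance()] — deterministic.
#'
#' @param a,b Nonempty nucleotide strings over `{A, C, G, T, N}`.
#' @param params An [alignment_params()] object.
#' @return An object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length strings with `-` for gaps), integer `score`,
#'   `n_match` (identical non-`N` aligned columns) and `length` (alignment
#'   columns).
#' @examples
#' aln <- nw_align("ACGTACGT", "ACGAACGT")
#' aln$score
#' genetic_distance(aln)
#' @export
nw_align <- function(a, b, params = alignment_params()) {
  stopifnot(inherits(params, "alignment_params"))
  for (s in list(a, b)) {
    if (!is.character(s) || length(s) != 1 || !nzchar(s)) {
      abort("sequences must be nonempty strings",
            class = "seqmds_validation_error")
    }
  }
  a <- toupper(a); b <- toupper(b)
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b)) {
    abort("sequences may only contain A/C/G/T/N",
          class = "seqmds_validation_error")
  }
  res <- nw_align_cpp(a, b, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  structure(res, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score", x$score, "| identity",
      sprintf("%d/%d (%.1f%%)", x$n_match, x$length,
              100 * x$n_match / x$length), "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Genetic distance of an aligned pair
#'
#' The dissimilarity used throughout the pipeline:
#' `1 - n_match / length`, i.e. one minus the fractional identity over the
#' full global alignment, with gap columns counted in the length. Always in
#' `[0, 1]`: 0 for identical sequences, 1 for an alignment with no matching
#' column.
#'
#' @param aln A `pairwise_alignment` from [nw_align()].
#' @return A numeric distance in `[0, 1]`.
#' @export
genetic_distance <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  1 - aln$n_match / aln$length
}
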