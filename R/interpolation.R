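#' Parameters for interpolative MDS placement
#'
#' Each out-of-sample read is placed against its `k_neighbors` nearest
#' in-sample anchors by a single-point majorization loop (the per-point
#' analogue of the Guttman update, with the anchors held fixed).
#'
#' @param k_neighbors Number of nearest in-sample anchors per point
#'   (default 10; `k = M`, all anchors, is supported).
#' @param max_iterations Per-point iteration cap.
#' @param tolerance Per-point relative stress-change stopping threshold.
#' @return An object of class `interp_params`.
#' @export
interp_params <- function(k_neighbors = 10L, max_iterations = 100L,
                          tolerance = 1e-8) {
  if (k_neighbors < 1 || max_iterations < 1 || tolerance <= 0) {
    abort("need k_neighbors >= 1, max_iterations >= 1, tolerance > 0",
          class = "seqmds_validation_error")
  }
  structure(
    list(k_neighbors = as.integer(k_neighbors),
         max_iterations = as.integer(max_iterations), tolerance = tolerance),
    class = "interp_params"
  )
}

#' Genetic distances from one query read to every in-sample anchor
#'
#' The on-the-fly alignment step of the interpolative pipeline: the query is
#' aligned against each of the M in-sample records (exactly M alignments,
#' counted in the ledger), yielding the distance vector from which the
#' nearest anchors are chosen.
#'
#' @param query A single residue string, or a one-row record tibble.
#' @param in_records Tibble of the M in-sample records.
#' @param params [alignment_params()].
#' @param ledger Optional [cost_ledger()]; `nw_alignments` += M.
#' @return Numeric vector of M genetic distances, named by anchor id.
#' @export
anchor_distances <- function(query, in_records, params = alignment_params(),
                             ledger = NULL) {
  if (is.data.frame(query)) query <- query$residues
  stopifnot(is.character(query), length(query) == 1)
  in_records <- validate_records(in_records, "in_records")
  m <- nrow(in_records)
  d <- nw_distance_pairs_cpp(
    c(query, in_records$residues),
    rep(1L, m), seq_len(m) + 1L,
    params$match, params$mismatch, params$gap_open, params$gap_extend
  )
  ledger_add(ledger, "nw_alignments", m)
  setNames(d, in_records$id)
}

#' Indices of the k nearest anchors
#'
#' @param distances Numeric vector of M anchor distances.
#' @param k Number of anchors to keep, `k <= M`. Ties are broken by lower
#'   index.
#' @return Integer vector of k indices, ordered by increasing distance.
#' @export
select_anchors <- function(distances, k) {
  if (k > length(distances)) {
    abort("k exceeds the number of anchors", class = "seqmds_validation_error")
  }
  order(distances, seq_along(distances))[seq_len(k)]
}

#' Place one point into a fixed embedding by majorizing its anchor stress
#'
#' Minimizes the single-point stress
#' \eqn{\sum_i (\delta_i - \|x - p_i\|)^2} over the point's position x, with
#' the k anchor positions \eqn{p_i} fixed, by the iteration
#' \eqn{x \leftarrow \frac{1}{k}\sum_i [\, p_i + \frac{\delta_i}{\max(\|x-p_i\|,\epsilon)} (x - p_i) \,]}
#' started from the mean of the anchor coordinates. The stress is
#' nonincreasing across iterations. A query at zero distance from an anchor
#' (an exact duplicate) is placed on that anchor directly, with no
#' iterations.
#'
#' @param deltas k-vector of target distances to the anchors.
#' @param anchors k x L matrix of fixed anchor coordinates.
#' @param params [interp_params()] (only the stopping rule is used here;
#'   anchor selection happens in the caller).
#' @param ledger Optional [cost_ledger()]; `majorization_iterations` is
#'   incremented by the iterations used.
#' @param anchor_indices Optional integer identities of the anchors,
#'   recorded in the result.
#' @return An object of class `interpolated_point`: list with `coords`
#'   (L-vector), `anchor_indices`, `point_stress`, `n_iterations` and the
#'   per-iteration `stress_trace`.
#' @export
interpolate_point <- function(deltas, anchors, params = interp_params(),
                              ledger = NULL, anchor_indices = NULL) {
  anchors <- as.matrix(anchors)
  if (any(!is.finite(deltas)) || any(!is.finite(anchors))) {
    abort("nonfinite interpolation input", class = "seqmds_validation_error")
  }
  k <- length(deltas)
  if (nrow(anchors) != k || k < 1) {
    abort("one anchor row per distance required",
          class = "seqmds_validation_error")
  }
  eps <- 1e-10
  point_stress_at <- function(x) {
    di <- sqrt(colSums((t(anchors) - x)^2))
    sum((deltas - di)^2)
  }

  if (min(deltas) == 0) {
    x <- anchors[which.min(deltas), ]
    res <- list(coords = x, anchor_indices = anchor_indices,
                point_stress = point_stress_at(x), n_iterations = 0L,
                stress_trace = point_stress_at(x))
    class(res) <- "interpolated_point"
    ledger_add(ledger, "majorization_iterations", 0)
    return(res)
  }

  x <- colMeans(anchors)
  # mean coinciding with an anchor at delta > 0 would put a zero in the
  # distance ratio; nudge it off before iterating
  if (any(sqrt(colSums((t(anchors) - x)^2)) < eps)) {
    x <- x + 1e-9
  }
  sigma <- point_stress_at(x)
  trace <- sigma
  iter <- 0L
  while (iter < params$max_iterations) {
    dx <- t(x - t(anchors))            # k x L rows x - p_i
    di <- pmax(sqrt(rowSums(dx^2)), eps)
    x <- colMeans(anchors + (deltas / di) * dx)
    iter <- iter + 1L
    sigma_new <- point_stress_at(x)
    trace <- c(trace, sigma_new)
    done <- sigma == 0 || abs(sigma - sigma_new) / sigma < params$tolerance
    sigma <- sigma_new
    if (done) break
  }
  ledger_add(ledger, "majorization_iterations", iter)
  structure(
    list(coords = x, anchor_indices = anchor_indices, point_stress = sigma,
         n_iterations = iter, stress_trace = trace),
    class = "interpolated_point"
  )
}

#' Interpolate all out-of-sample reads into a trained embedding
#'
#' For each out-of-sample record: align against all M in-sample records
#' ([anchor_distances()]), keep the k nearest anchors, and place the point
#' by [interpolate_point()]. In-sample coordinates are never modified.
#' Points are processed independently, so the result is identical for any
#' processing order, chunking or worker count. Total alignment cost is
#' exactly `(N - M) * M`.
#'
#' @param in_embedding [embedding()] of the in-sample records (rows aligned
#'   with `in_records`).
#' @param in_records,out_records Record tibbles; ids must not collide.
#' @param aln_params [alignment_params()].
#' @param params [interp_params()].
#' @param ledger Optional [cost_ledger()].
#' @param block_size Out-of-sample points per work block.
#' @param workers Parallel worker processes (forked).
#' @return An [embedding()] with `nrow(in_records) + nrow(out_records)`
#'   rows: the in-sample rows first, unchanged, then one row per
#'   out-of-sample record in input order.
#' @examples
#' recs <- generate_families(n_families = 3, members_per_family = 10, seed = 2)
#' sp <- split_sample(nrow(recs), 15, seed = 3)
#' ins <- recs[sp$in_sample, ]; outs <- recs[sp$out_of_sample, ]
#' fit <- run_smacof(build_distance_matrix(ins), mds_params(seed = 1))
#' full <- run_interpolation(fit$embedding, ins, outs)
#' @export
run_interpolation <- function(in_embedding, in_records, out_records,
                              aln_params = alignment_params(),
                              params = interp_params(), ledger = NULL,
                              block_size = 500L, workers = 1L) {
  in_records <- validate_records(in_records, "in_records")
  if (nrow(in_embedding) != nrow(in_records)) {
    abort("in_embedding rows must correspond to in_records",
          class = "seqmds_validation_error")
  }
  if (is.null(out_records) || nrow(out_records) == 0) {
    return(in_embedding)
  }
  out_records <- validate_records(out_records, "out_records")
  if (any(out_records$id %in% in_records$id)) {
    abort("id collision between in-sample and out-of-sample sets",
          class = "seqmds_validation_error")
  }
  m <- nrow(in_records)
  k <- min(params$k_neighbors, m)
  L <- ncol(in_embedding)
  in_coords <- unclass(in_embedding)

  one <- function(i) {
    d_all <- nw_distance_pairs_cpp(
      c(out_records$residues[i], in_records$residues),
      rep(1L, m), seq_len(m) + 1L,
      aln_params$match, aln_params$mismatch,
      aln_params$gap_open, aln_params$gap_extend
    )
    sel <- select_anchors(d_all, k)
    pt <- interpolate_point(d_all[sel], in_coords[sel, , drop = FALSE],
                            params, ledger = NULL, anchor_indices = sel)
    c(pt$coords, pt$n_iterations)
  }
  res <- chunked_map_numeric(
    nrow(out_records), block_size, workers,
    function(lo, hi) unlist(lapply(lo:hi, one), use.names = FALSE)
  )
  res <- matrix(res, ncol = L + 1, byrow = TRUE)
  ledger_add(ledger, "nw_alignments", nrow(out_records) * m)
  ledger_add(ledger, "majorization_iterations", sum(res[, L + 1]))
  embedding(rbind(in_coords, res[, seq_len(L), drop = FALSE]),
            c(rownames(in_embedding), out_records$id))
}
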