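#' Embedding configuration
#'
#' An `embedding` is an n x L numeric matrix of Cartesian coordinates, one
#' row per record, with record ids as rownames. Produced by [run_smacof()]
#' and [run_interpolation()].
#'
#' @param coords Numeric matrix with finite entries.
#' @param ids Character ids, one per row.
#' @return A matrix of class `embedding`.
#' @export
embedding <- function(coords, ids = rownames(coords)) {
  coords <- as.matrix(coords)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  if (length(ids) != nrow(coords)) {
    abort("one id per coordinate row required", class = "seqmds_validation_error")
  }
  if (any(!is.finite(coords))) {
    abort("embedding coordinates must be finite", class = "seqmds_validation_error")
  }
  rownames(coords) <- ids
  colnames(coords) <- embedding_dim_names(ncol(coords))
  class(coords) <- c("embedding", class(coords))
  coords
}

embedding_dim_names <- function(L) {
  if (L <= 3) c("x", "y", "z")[seq_len(L)] else paste0("dim", seq_len(L))
}

#' @export
print.embedding <- function(x, ...) {
  cat("<embedding>", nrow(x), "points in", ncol(x), "dimensions\n")
  print(head(unclass(x), 4))
  if (nrow(x) > 4) cat("...", nrow(x) - 4, "more points\n")
  invisible(x)
}

#' Parameters for full SMACOF multidimensional scaling
#'
#' @param n_dim Target embedding dimensionality L (default 3, matching 3-D
#'   visualization of sequence space).
#' @param max_iterations Iteration cap for the majorization loop.
#' @param tolerance Relative stress-change stopping threshold.
#' @param seed Integer seed; consumed only by `init = "random"`.
#' @param init Initial configuration: `"torgerson"` (classical scaling on
#'   the dissimilarities; deterministic, and immune to the cluster-swap
#'   local minima random starts fall into on well-separated clusters) or
#'   `"random"` (i.i.d. uniform in `[-0.5, 0.5]^L` from `seed`).
#' @return An object of class `mds_params`.
#' @export
mds_params <- function(n_dim = 3L, max_iterations = 500L, tolerance = 1e-6,
                       seed = 42L, init = c("torgerson", "random")) {
  init <- match.arg(init)
  if (n_dim < 1 || max_iterations < 1 || tolerance <= 0) {
    abort("need n_dim >= 1, max_iterations >= 1, tolerance > 0",
          class = "seqmds_validation_error")
  }
  structure(
    list(n_dim = as.integer(n_dim), max_iterations = as.integer(max_iterations),
         tolerance = tolerance, seed = as.integer(seed), init = init),
    class = "mds_params"
  )
}

#' Raw Kruskal stress of a configuration
#'
#' The MDS objective with uniform weights:
#' \eqn{\sigma(X) = \sum_{i<j} (\delta_{ij} - d_{ij}(X))^2}, where
#' \eqn{d_{ij}(X)} is the Euclidean distance between rows i and j of the
#' configuration.
#'
#' @param delta A [dist_matrix()] of target dissimilarities.
#' @param x An [embedding()] (or bare coordinate matrix) with matching row
#'   count.
#' @return The raw stress, a nonnegative scalar.
#' @export
stress <- function(delta, x) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(delta)) {
    abort("embedding rows must match distance matrix dimension",
          class = "seqmds_validation_error")
  }
  sum((as.dist(unclass(delta)) - dist(x))^2)
}

#' One Guttman majorization update
#'
#' The closed-form SMACOF coordinate update for uniform weights:
#' `X' = B(X) X / n` with `b_ij = -delta_ij / max(d_ij(X), eps)` off the
#' diagonal and `b_ii = -sum_{j != i} b_ij`. Guarantees
#' `stress(X') <= stress(X)`. Coincident points are guarded by replacing
#' `d_ij < 1e-10` with `1e-10` in the ratio.
#'
#' @inheritParams stress
#' @return The updated configuration (same class and ids as `x`).
#' @export
guttman_step <- function(delta, x) {
  ids <- rownames(x)
  x <- as.matrix(x)
  if (nrow(x) != nrow(delta)) {
    abort("embedding rows must match distance matrix dimension",
          class = "seqmds_validation_error")
  }
  n <- nrow(x)
  d <- as.matrix(dist(x))
  d[d < 1e-10] <- 1e-10
  B <- -unclass(delta) / d
  diag(B) <- 0
  diag(B) <- -rowSums(B)
  embedding((B %*% x) / n, ids)
}

#' Full metric MDS by SMACOF stress majorization
#'
#' Embeds a genetic distance matrix into L-dimensional Cartesian space by
#' iterating [guttman_step()] from the initial configuration chosen in
#' [mds_params()] (classical scaling by default) until the relative stress
#' change falls below `tolerance` or `max_iterations` is reached. Stress is
#' guaranteed nonincreasing across iterations. This is the O(n^2)-per-
#' iteration full calculation applied to the whole sample in the basic
#' pipeline, or to the in-sample subset in the interpolative pipeline.
#'
#' @param delta A [dist_matrix()]; at least 2 points with some nonzero
#'   off-diagonal dissimilarity.
#' @param params An [mds_params()] object.
#' @param ledger Optional [cost_ledger()]; `smacof_iterations` is
#'   incremented by the number of Guttman updates performed.
#' @return An object of class `mds_fit`: list with `embedding` (an
#'   [embedding()]), `final_stress`, `normalized_stress` (raw stress divided
#'   by `sum(delta^2)` over pairs), `n_iterations` and the per-iteration
#'   `stress_trace` (element 1 is the stress of the initial configuration).
#' @examples
#' fix <- generate_geometric(n = 30, n_blobs = 3, seed = 7)
#' fit <- run_smacof(fix$delta, mds_params(seed = 1))
#' glance(fit)
#' @export
run_smacof <- function(delta, params = mds_params(), ledger = NULL) {
  stopifnot(inherits(delta, "dist_matrix"), inherits(params, "mds_params"))
  n <- nrow(delta)
  if (n < 2) {
    abort("need at least 2 points for MDS", class = "seqmds_degenerate_error")
  }
  denom <- sum(as.dist(unclass(delta))^2)
  if (denom == 0) {
    abort("all dissimilarities are zero: degenerate input for MDS",
          class = "seqmds_degenerate_error")
  }
  L <- params$n_dim
  x <- if (params$init == "torgerson") {
    embedding(torgerson_init(delta, L), dm_ids(delta))
  } else {
    withr::with_seed(
      params$seed,
      embedding(matrix(runif(n * L) - 0.5, n, L), dm_ids(delta))
    )
  }
  sigma <- stress(delta, x)
  trace <- sigma
  iter <- 0L
  while (iter < params$max_iterations) {
    x <- guttman_step(delta, x)
    iter <- iter + 1L
    sigma_new <- stress(delta, x)
    trace <- c(trace, sigma_new)
    if (sigma == 0 || abs(sigma - sigma_new) / sigma < params$tolerance) {
      sigma <- sigma_new
      break
    }
    sigma <- sigma_new
  }
  ledger_add(ledger, "smacof_iterations", iter)
  structure(
    list(embedding = x, final_stress = sigma,
         normalized_stress = sigma / denom, n_iterations = iter,
         stress_trace = trace, params = params),
    class = "mds_fit"
  )
}

#' @export
print.mds_fit <- function(x, ...) {
  cat("<mds_fit>", nrow(x$embedding), "points in", ncol(x$embedding),
      "dimensions\n")
  cat(sprintf("  raw stress %.6g (normalized %.3g) after %d iterations\n",
              x$final_stress, x$normalized_stress, x$n_iterations))
  invisible(x)
}

# classical scaling (double-centered squared dissimilarities); pads with
# zero columns when fewer than L positive eigenvalues exist
torgerson_init <- function(delta, L) {
  d2 <- unclass(delta)^2
  n <- nrow(d2)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% d2 %*% J
  eig <- eigen(B, symmetric = TRUE)
  pos <- pmax(eig$values[seq_len(min(L, n))], 0)
  x <- eig$vectors[, seq_along(pos), drop = FALSE] %*% diag(sqrt(pos),
                                                            length(pos))
  if (ncol(x) < L) x <- cbind(x, matrix(0, n, L - ncol(x)))
  x
}

#' @rdname run_smacof
#' @param x An `mds_fit`.
#' @param ... Unused.
#' @export
tidy.mds_fit <- function(x, ...) tidy_embedding(x$embedding)

tidy_embedding <- function(emb, labels = NULL) {
  out <- dplyr::bind_cols(
    tibble(id = rownames(emb)),
    as_tibble(unclass(emb))
  )
  if (!is.null(labels)) out$label <- labels
  out
}

#' @rdname run_smacof
#' @export
glance.mds_fit <- function(x, ...) {
  tibble(
    n_points = nrow(x$embedding),
    n_dim = ncol(x$embedding),
    final_stress = x$final_stress,
    normalized_stress = x$normalized_stress,
    n_iterations = x$n_iterations
  )
}
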