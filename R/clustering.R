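#' k-medoids clustering of a genetic distance matrix
#'
#' Partitions the reads into C clusters by PAM (partitioning around
#' medoids): a greedy BUILD phase followed by SWAP steps until no medoid
#' exchange lowers the total within-cluster distance to medoids. PAM
#' consumes the pairwise distance matrix directly — no coordinates needed —
#' which is exactly the interface the pipeline's distance stage provides.
#' The computation is deterministic; `seed` is recorded in the result for
#' the run manifest but PAM itself draws no random numbers.
#'
#' @param delta A [dist_matrix()].
#' @param n_clusters Cluster count C, with `2 <= C <= n`.
#' @param seed Integer, recorded for provenance.
#' @return An object of class `cluster_assignment`: list with integer
#'   `labels` in `1..C` named by record id, `medoid_indices` (each medoid's
#'   label is its own cluster), `n_clusters`, `total_cost` (sum of distances
#'   of points to their medoids) and `seed`.
#' @examples
#' recs <- generate_families(n_families = 2, members_per_family = 5, seed = 1)
#' delta <- build_distance_matrix(recs)
#' kmedoids_cluster(delta, 2)
#' @export
kmedoids_cluster <- function(delta, n_clusters, seed = 0L) {
  stopifnot(inherits(delta, "dist_matrix"))
  n <- nrow(delta)
  if (n_clusters < 2 || n_clusters > n) {
    abort("cluster count must satisfy 2 <= C <= n",
          class = "seqmds_validation_error")
  }
  if (n_clusters == n) {
    # every point its own medoid, total cost 0 (pam requires k < n)
    labels <- seq_len(n)
    medoids <- seq_len(n)
  } else {
    fit <- cluster::pam(as.dist(unclass(delta)), k = n_clusters, diss = TRUE,
                        keep.diss = FALSE)
    labels <- as.integer(fit$clustering)
    medoids <- as.integer(fit$id.med)
  }
  total_cost <- sum(unclass(delta)[cbind(seq_len(n), medoids[labels])])
  structure(
    list(labels = setNames(labels, dm_ids(delta)),
         medoid_indices = medoids, n_clusters = as.integer(n_clusters),
         total_cost = total_cost, seed = as.integer(seed)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", x$n_clusters, "clusters over",
      length(x$labels), "points; total cost", format(x$total_cost), "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' @rdname kmedoids_cluster
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(id = names(x$labels), label = unname(x$labels),
         is_medoid = seq_along(x$labels) %in% x$medoid_indices)
}

#' @rdname kmedoids_cluster
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(n_points = length(x$labels), n_clusters = x$n_clusters,
         total_cost = x$total_cost)
}

#' Propagate cluster labels to interpolated points
#'
#' Out-of-sample reads never enter the k-medoids run (that would require
#' their pairwise distances and break the cost contract); instead each
#' interpolated point takes the label of the medoid nearest to it in the
#' embedded Euclidean space. In-sample labels are unchanged.
#'
#' @param assignment A `cluster_assignment` over the in-sample set.
#' @param in_embedding [embedding()] of the in-sample points the assignment
#'   was computed for.
#' @param full_embedding [embedding()] of all N points (in-sample ids must
#'   be present; typically from [run_interpolation()]).
#' @return Integer label vector named by id, in `full_embedding` row order.
#' @export
assign_interpolated_labels <- function(assignment, in_embedding,
                                       full_embedding) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (ncol(in_embedding) != ncol(full_embedding)) {
    abort("embedding dimensions disagree", class = "seqmds_validation_error")
  }
  if (length(assignment$labels) != nrow(in_embedding)) {
    abort("assignment must cover the in-sample embedding",
          class = "seqmds_validation_error")
  }
  med_coords <- unclass(in_embedding)[assignment$medoid_indices, , drop = FALSE]
  med_labels <- assignment$labels[assignment$medoid_indices]
  ids <- rownames(full_embedding)
  in_pos <- match(ids, rownames(in_embedding))
  labels <- integer(length(ids))
  is_in <- !is.na(in_pos)
  labels[is_in] <- assignment$labels[in_pos[is_in]]
  if (any(!is_in)) {
    out_coords <- unclass(full_embedding)[!is_in, , drop = FALSE]
    # squared Euclidean distance of every out point to every medoid
    d2 <- outer(rowSums(out_coords^2), rowSums(med_coords^2), "+") -
      2 * out_coords %*% t(med_coords)
    labels[!is_in] <- med_labels[max.col(-d2, ties.method = "first")]
  }
  setNames(as.integer(labels), ids)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' from the pair-counting contingency table: 1 for identical partitions
#' (up to label renaming), approximately 0 for independent ones.
#'
#' @param labels_a,labels_b Label vectors of equal length (>= 2); label
#'   values are arbitrary.
#' @return The ARI, a scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 2) {
    abort("labelings must have equal length >= 2",
          class = "seqmds_validation_error")
  }
  as.numeric(mclust::adjustedRandIndex(labels_a, labels_b))
}

#' Compare two point configurations by Procrustes superimposition
#'
#' MDS output is determined only up to translation, rotation, reflection
#' and uniform scale, so configurations are compared after removing all
#' four: both are centered and scaled to unit root-mean-square size, then
#' the orthogonal transform (reflections allowed) and residual scale that
#' best superimpose the second onto the first are fitted by SVD. The
#' reported `rmsd` is the root-mean-square residual between the two
#' normalized configurations — symmetric in its arguments, zero exactly
#' when the configurations are similarity-transform equivalent, and
#' directly comparable to the unit RMS size of the configurations.
#'
#' @param x,y [embedding()]s (or bare matrices) with the same row count and
#'   dimension; when both carry ids the row order must agree.
#' @return An object of class `procrustes_report`: list with `rmsd` (in
#'   units of the unit-RMS normalized configurations), `scale` (the fitted
#'   uniform scale mapping the original `y` onto the original `x`) and
#'   `rotation` (the fitted orthogonal matrix).
#' @export
procrustes_compare <- function(x, y) {
  xm <- as.matrix(x); ym <- as.matrix(y)
  if (!all(dim(xm) == dim(ym))) {
    abort("configurations must have identical dimensions",
          class = "seqmds_validation_error")
  }
  if (!is.null(rownames(xm)) && !is.null(rownames(ym)) &&
      !identical(rownames(xm), rownames(ym))) {
    abort("configuration row ids disagree (rows must be aligned by id)",
          class = "seqmds_validation_error")
  }
  n <- nrow(xm)
  xc <- sweep(xm, 2, colMeans(xm))
  yc <- sweep(ym, 2, colMeans(ym))
  rms_x <- sqrt(sum(xc^2) / n)
  rms_y <- sqrt(sum(yc^2) / n)
  if (rms_x == 0 && rms_y == 0) {
    return(structure(list(rmsd = 0, scale = 1,
                          rotation = diag(ncol(xm))),
                     class = "procrustes_report"))
  }
  if (rms_x == 0 || rms_y == 0) {
    # one configuration degenerate to a point: no similarity transform can
    # superimpose them; residual is the full size of the other
    return(structure(list(rmsd = 1, scale = 0, rotation = diag(ncol(xm))),
                     class = "procrustes_report"))
  }
  xn <- xc / rms_x
  yn <- yc / rms_y
  sv <- svd(crossprod(yn, xn))
  rotation <- sv$u %*% t(sv$v)
  trace <- sum(sv$d)
  s_norm <- trace / n               # optimal scale between unit-RMS configs
  resid <- xn - s_norm * (yn %*% rotation)
  structure(
    list(rmsd = sqrt(sum(resid^2) / n),
         scale = s_norm * rms_x / rms_y,
         rotation = rotation),
    class = "procrustes_report"
  )
}

#' @export
print.procrustes_report <- function(x, ...) {
  cat(sprintf("<procrustes_report> rmsd %.6g (unit-RMS units), scale %.4g\n",
              x$rmsd, x$scale))
  invisible(x)
}
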