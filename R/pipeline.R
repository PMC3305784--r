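#' Configuration for a full or interpolative pipeline run
#'
#' Bundles every knob of the two pipelines so a run is reproducible from
#' its manifest: input, mode, in-sample size, all stage parameters and all
#' seeds.
#'
#' @param fasta Path to the input FASTA file, or a record tibble (as from
#'   [read_fasta()] or [generate_families()]) used directly.
#' @param mode `"full"` (all-pairs distances + full MDS over all N reads)
#'   or `"interpolative"` (full treatment of an M-read in-sample subset,
#'   remaining reads placed by interpolation).
#' @param n_clusters Cluster count C for k-medoids.
#' @param points_path Output path for the points file
#'   ([write_points_file()]).
#' @param m_in_sample In-sample size M (interpolative mode only;
#'   `1 <= M < N`).
#' @param alignment [alignment_params()].
#' @param mds [mds_params()] (carries the MDS initialization seed).
#' @param interpolation [interp_params()].
#' @param seed_split Seed for the in-/out-of-sample split.
#' @param seed_cluster Seed recorded with the k-medoids run.
#' @param workers Parallel workers for the distance and interpolation maps.
#' @param block_size Work-block size for the chunked maps.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, mode = c("full", "interpolative"),
                            n_clusters, points_path = NULL,
                            m_in_sample = NULL,
                            alignment = alignment_params(),
                            mds = mds_params(),
                            interpolation = interp_params(),
                            seed_split = 1L, seed_cluster = 1L,
                            workers = 1L, block_size = 5000L) {
  mode <- match.arg(mode)
  if (mode == "interpolative" && is.null(m_in_sample)) {
    abort("interpolative mode requires `m_in_sample`",
          class = "seqmds_validation_error")
  }
  structure(
    list(fasta = fasta, mode = mode, n_clusters = as.integer(n_clusters),
         points_path = points_path, m_in_sample = m_in_sample,
         alignment = alignment, mds = mds, interpolation = interpolation,
         seed_split = as.integer(seed_split),
         seed_cluster = as.integer(seed_cluster),
         workers = as.integer(workers), block_size = as.integer(block_size)),
    class = "pipeline_config"
  )
}

load_pipeline_records <- function(config) {
  if (is.data.frame(config$fasta)) {
    validate_records(config$fasta)
  } else {
    read_fasta(config$fasta)
  }
}

#' Run the basic (full) clustering pipeline
#'
#' read, deduplicate, all-pairs Needleman-Wunsch distances, full SMACOF
#' MDS, k-medoids clustering, points-file export. The distance and scaling
#' stages are O(N^2): exactly `N(N-1)/2` alignments are executed over the N
#' unique reads, and the count is verified in the returned manifest.
#'
#' @param config A [pipeline_config()] with `mode = "full"`.
#' @return An object of class `run_manifest`: list with the config, `n_total`
#'   (reads as input), `n_unique` (after deduplication), `m_in_sample`
#'   (equal to `n_unique` in full mode), the [cost_ledger()] counts, the
#'   final MDS stress values, the combined `embedding`, the `labels` vector
#'   (named by id, in post-deduplication order) and `points_path` if a
#'   points file was written.
#' @examples
#' recs <- generate_families(n_families = 2, members_per_family = 6, seed = 5)
#' man <- run_full_pipeline(pipeline_config(recs, "full", n_clusters = 2))
#' glance(man)
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode != "full") {
    abort("config mode must be 'full'", class = "seqmds_validation_error")
  }
  t0 <- proc.time()[["elapsed"]]
  with_cleanup(config$points_path, {
    records <- load_pipeline_records(config)
    n_total <- nrow(records)
    uniq <- deduplicate(records)
    ledger <- cost_ledger()
    delta <- build_distance_matrix(uniq, config$alignment, ledger,
                                   block_size = config$block_size,
                                   workers = config$workers)
    fit <- run_smacof(delta, config$mds, ledger)
    assignment <- kmedoids_cluster(delta, config$n_clusters,
                                   config$seed_cluster)
    labels <- assignment$labels
    if (!is.null(config$points_path)) {
      write_points_file(fit$embedding, labels, config$points_path)
    }
    new_manifest(config, n_total, nrow(uniq), nrow(uniq), ledger, fit,
                 fit$embedding, labels,
                 proc.time()[["elapsed"]] - t0)
  })
}

#' Run the scaled-up (interpolative) clustering pipeline
#'
#' The input is split into an in-sample set of size M and an out-of-sample
#' set of size N - M. Only the in-sample set receives the full O(M^2)
#' treatment (all-pairs distances, SMACOF, k-medoids); every out-of-sample
#' read is then placed by [run_interpolation()] with on-the-fly alignments
#' against the M anchors and labeled by its nearest medoid in embedded
#' space. Total alignment cost is exactly `M(M-1)/2 + (N-M)*M`.
#'
#' @param config A [pipeline_config()] with `mode = "interpolative"` and
#'   `m_in_sample` set.
#' @return A `run_manifest` (see [run_full_pipeline()]); `labels` and the
#'   `embedding` cover all N unique reads in post-deduplication input
#'   order.
#' @export
run_interpolative_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode != "interpolative") {
    abort("config mode must be 'interpolative'",
          class = "seqmds_validation_error")
  }
  t0 <- proc.time()[["elapsed"]]
  with_cleanup(config$points_path, {
    records <- load_pipeline_records(config)
    n_total <- nrow(records)
    uniq <- deduplicate(records)
    n <- nrow(uniq)
    m <- config$m_in_sample
    if (m >= n) {
      abort(sprintf("m_in_sample (%d) must be smaller than the number of unique reads (%d)",
                    m, n),
            class = "seqmds_validation_error")
    }
    split <- split_sample(n, m, config$seed_split)
    ins <- uniq[split$in_sample, ]
    outs <- uniq[split$out_of_sample, ]
    ledger <- cost_ledger()
    delta <- build_distance_matrix(ins, config$alignment, ledger,
                                   block_size = config$block_size,
                                   workers = config$workers)
    fit <- run_smacof(delta, config$mds, ledger)
    assignment <- kmedoids_cluster(delta, config$n_clusters,
                                   config$seed_cluster)
    combined <- run_interpolation(fit$embedding, ins, outs,
                                  aln_params = config$alignment,
                                  params = config$interpolation,
                                  ledger = ledger,
                                  block_size = config$block_size,
                                  workers = config$workers)
    labels <- assign_interpolated_labels(assignment, fit$embedding, combined)
    # back to post-deduplication input order
    ord <- match(uniq$id, rownames(combined))
    combined <- embedding(unclass(combined)[ord, , drop = FALSE], uniq$id)
    labels <- labels[ord]
    if (!is.null(config$points_path)) {
      write_points_file(combined, labels, config$points_path)
    }
    new_manifest(config, n_total, n, m, ledger, fit, combined, labels,
                 proc.time()[["elapsed"]] - t0)
  })
}

with_cleanup <- function(points_path, expr) {
  tryCatch(expr, error = function(e) {
    if (!is.null(points_path) && file.exists(points_path)) {
      unlink(points_path)
    }
    stop(e)
  })
}

new_manifest <- function(config, n_total, n_unique, m, ledger, fit,
                         embedding, labels, wall_time) {
  structure(
    list(config = config, n_total = n_total, n_unique = n_unique,
         m_in_sample = m, ledger = ledger_counts(ledger),
         final_stress = fit$final_stress,
         normalized_stress = fit$normalized_stress,
         mds_iterations = fit$n_iterations,
         embedding = embedding, labels = labels,
         points_path = config$points_path, wall_time = wall_time),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$config$mode, "pipeline\n")
  cat("  reads:", x$n_total, "input,", x$n_unique, "unique; in-sample M =",
      x$m_in_sample, "\n")
  cat("  NW alignments:", x$ledger$nw_alignments,
      "| SMACOF iterations:", x$ledger$smacof_iterations,
      "| interpolation iterations:", x$ledger$majorization_iterations, "\n")
  cat(sprintf("  in-sample stress: %.6g (normalized %.3g)\n",
              x$final_stress, x$normalized_stress))
  if (!is.null(x$points_path)) cat("  points file:", x$points_path, "\n")
  cat(sprintf("  wall time: %.2fs (informational)\n", x$wall_time))
  invisible(x)
}

#' @rdname run_full_pipeline
#' @param x A `run_manifest`.
#' @param ... Unused.
#' @export
glance.run_manifest <- function(x, ...) {
  dplyr::bind_cols(
    tibble(mode = x$config$mode, n_total = x$n_total,
           n_unique = x$n_unique, m_in_sample = x$m_in_sample),
    x$ledger,
    tibble(final_stress = x$final_stress,
           normalized_stress = x$normalized_stress)
  )
}

#' @rdname run_full_pipeline
#' @export
tidy.run_manifest <- function(x, ...) {
  tidy_embedding(x$embedding, labels = unname(x$labels))
}
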