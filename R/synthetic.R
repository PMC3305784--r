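BASES <- c("A", "C", "G", "T")

#' Generate synthetic sequence families with known labels
#'
#' Emulates a multi-family amplicon read set (the statistical structure the
#' pipeline assumes): C distinct ancestor sequences are drawn uniformly
#' over `{A,C,G,T}` and re-drawn until every ancestor pair differs in at
#' least `min_ancestor_distance` of its sites; each family member is then
#' derived from its ancestor by independent per-site substitutions (to a
#' uniformly chosen different base) and single-site indels (insert or
#' delete with equal probability). Within-family divergence is therefore
#' much smaller than between-family divergence. Optionally a fraction of
#' members is duplicated verbatim, exercising the deduplication stage.
#' Fully deterministic given `seed`.
#'
#' @param n_families Number of families C.
#' @param members_per_family Members drawn per family.
#' @param ancestor_length_range Integer range of ancestor lengths in
#'   nucleotides (default 120–180, i.e. short reads under 200 bases).
#' @param substitution_rate Per-site substitution probability (default
#'   0.02).
#' @param indel_rate Per-site indel probability (default 0.005).
#' @param min_ancestor_distance Minimum pairwise fractional difference
#'   between ancestors (default 0.30).
#' @param duplicate_fraction Fraction of members appended again as exact
#'   copies (default 0).
#' @param seed Integer RNG seed.
#' @return A record tibble (`id`, `residues`, `truth_label`) with family
#'   labels `0 .. C-1`; duplicated members carry the same label under a
#'   fresh id.
#' @examples
#' recs <- generate_families(n_families = 3, members_per_family = 5, seed = 1)
#' dplyr::count(recs, truth_label)
#' @export
generate_families <- function(n_families = 3L, members_per_family = 50L,
                              ancestor_length_range = c(120L, 180L),
                              substitution_rate = 0.02, indel_rate = 0.005,
                              min_ancestor_distance = 0.30,
                              duplicate_fraction = 0, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1 ||
      duplicate_fraction < 0 || duplicate_fraction >= 1) {
    abort("rates must lie in [0, 1)", class = "seqmds_validation_error")
  }
  if (max(ancestor_length_range) >= 200) {
    abort("ancestor lengths must stay below 200 nt",
          class = "seqmds_validation_error")
  }
  withr::with_seed(seed, {
    ancestors <- draw_ancestors(n_families, ancestor_length_range,
                                min_ancestor_distance)
    fams <- purrr::map(seq_len(n_families), function(f) {
      members <- purrr::map_chr(
        seq_len(members_per_family),
        function(i) mutate_sequence(ancestors[[f]], substitution_rate,
                                    indel_rate)
      )
      tibble(
        id = sprintf("fam%d_seq%03d", f - 1L, seq_len(members_per_family)),
        residues = members,
        truth_label = f - 1L
      )
    })
    out <- dplyr::bind_rows(fams)
    n_dup <- round(duplicate_fraction * nrow(out))
    if (n_dup > 0) {
      src <- sample.int(nrow(out), n_dup)
      dups <- out[src, ]
      dups$id <- paste0(dups$id, "_dup", seq_len(n_dup))
      out <- dplyr::bind_rows(out, dups)
    }
    out
  })
}

draw_ancestors <- function(n_families, length_range, min_distance,
                           max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    lens <- sample(seq.int(length_range[1], length_range[2]), n_families,
                   replace = TRUE)
    anc <- lapply(lens, function(len) sample(BASES, len, replace = TRUE))
    if (n_families == 1 || ancestors_separated(anc, min_distance)) {
      return(lapply(anc, paste, collapse = ""))
    }
  }
  abort(sprintf("could not draw %d ancestors with pairwise difference >= %.2f",
                n_families, min_distance),
        class = "seqmds_generation_error")
}

# fractional difference between two base vectors: mismatches over the
# shared prefix plus the length difference, relative to the longer length
ancestors_separated <- function(anc, min_distance) {
  for (i in seq_along(anc)) {
    for (j in seq_len(i - 1L)) {
      a <- anc[[i]]; b <- anc[[j]]
      k <- min(length(a), length(b))
      diff <- sum(a[seq_len(k)] != b[seq_len(k)]) +
        abs(length(a) - length(b))
      if (diff / max(length(a), length(b)) < min_distance) return(FALSE)
    }
  }
  TRUE
}

mutate_sequence <- function(ancestor, substitution_rate, indel_rate) {
  repeat {
    chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
    n <- length(chars)
    sub_at <- which(runif(n) < substitution_rate)
    for (i in sub_at) {
      chars[i] <- sample(setdiff(BASES, chars[i]), 1)
    }
    indel_at <- which(runif(n) < indel_rate)
    if (length(indel_at) > 0) {
      is_insert <- runif(length(indel_at)) < 0.5
      ins_sites <- indel_at[is_insert]
      del_sites <- indel_at[!is_insert]
      if (length(ins_sites) > 0) {
        chars[ins_sites] <- paste0(sample(BASES, length(ins_sites),
                                          replace = TRUE),
                                   chars[ins_sites])
      }
      chars[del_sites] <- ""
    }
    out <- paste(chars, collapse = "")
    if (nzchar(out)) return(out)
  }
}

#' Generate an exactly embeddable geometric distance fixture
#'
#' Draws n points as Gaussian blobs in the unit cube of dimension L (blob
#' centers re-drawn until pairwise separation is at least `6 * blob_sd`)
#' and returns their exact Euclidean distance matrix, scaled into `[0, 1]`
#' by its maximum. Because the distances come from actual coordinates, a
#' zero-stress MDS optimum exists, which makes the fixture an exact oracle
#' for SMACOF and interpolation: the recovered configuration can be checked
#' against `true_coords` by Procrustes comparison.
#'
#' @param n Number of points.
#' @param n_blobs Number of blobs (clusters); points are split across blobs
#'   as evenly as possible.
#' @param n_dim Dimension L (default 3).
#' @param blob_sd Within-blob standard deviation per coordinate (default
#'   0.05).
#' @param seed Integer RNG seed.
#' @return A list with `true_coords` (an [embedding()]), `delta` (a
#'   [dist_matrix()] of scaled Euclidean distances), `true_labels` (integer
#'   blob memberships `1..n_blobs` named by id) and `scale_factor` (the
#'   divisor used, so `delta * scale_factor` restores original distances).
#' @examples
#' fix <- generate_geometric(n = 40, n_blobs = 4, seed = 9)
#' fit <- run_smacof(fix$delta, mds_params(seed = 2))
#' procrustes_compare(fit$embedding, fix$true_coords)
#' @export
generate_geometric <- function(n, n_blobs = 1L, n_dim = 3L, blob_sd = 0.05,
                               seed = 1L) {
  if (n < n_blobs || n_blobs < 1) {
    abort("need n >= n_blobs >= 1", class = "seqmds_validation_error")
  }
  withr::with_seed(seed, {
    centers <- draw_blob_centers(n_blobs, n_dim, 6 * blob_sd)
    sizes <- rep(n %/% n_blobs, n_blobs) +
      (seq_len(n_blobs) <= n %% n_blobs)
    labels <- rep(seq_len(n_blobs), sizes)
    coords <- centers[labels, , drop = FALSE] +
      matrix(rnorm(n * n_dim, sd = blob_sd), n, n_dim)
    ids <- sprintf("pt%04d", seq_len(n))
    d <- as.matrix(dist(coords))
    scale_factor <- max(d)
    if (scale_factor == 0) scale_factor <- 1
    list(
      true_coords = embedding(coords, ids),
      delta = dist_matrix(d / scale_factor, ids),
      true_labels = setNames(labels, ids),
      scale_factor = scale_factor
    )
  })
}

draw_blob_centers <- function(n_blobs, n_dim, min_sep, max_tries = 1000L) {
  if (n_blobs == 1) return(matrix(runif(n_dim), 1, n_dim))
  for (try in seq_len(max_tries)) {
    centers <- matrix(runif(n_blobs * n_dim), n_blobs, n_dim)
    if (min(dist(centers)) >= min_sep) return(centers)
  }
  abort(sprintf("could not place %d blob centers with separation >= %.3f",
                n_blobs, min_sep),
        class = "seqmds_generation_error")
}
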