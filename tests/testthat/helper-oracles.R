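# Independent oracles used to freeze expected values. Each takes a route
# disjoint from the implementation it checks: exhaustive enumeration for
# alignment scores, direct double loops for stress/ARI, closed forms for
# Procrustes, brute force for medoids.

# Maximum global-alignment score by enumerating every alignment as a move
# sequence (diagonal / vertical / horizontal), scoring affine gaps from the
# previous move. No dynamic programming: the recursion visits every path.
oracle_nw_score <- function(a, b, params = alignment_params()) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  go <- params$gap_open; ge <- params$gap_extend
  rec <- function(i, j, prev) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- if (av[i + 1] == bv[j + 1] && av[i + 1] != "N") {
        params$match
      } else {
        params$mismatch
      }
      best <- max(best, s + rec(i + 1, j + 1, 0L))
    }
    if (i < n) {
      cost <- if (prev == 1L) ge else go + ge
      best <- max(best, rec(i + 1, j, 1L) - cost)
    }
    if (j < m) {
      cost <- if (prev == 2L) ge else go + ge
      best <- max(best, rec(i, j + 1, 2L) - cost)
    }
    best
  }
  rec(0L, 0L, 0L)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# raw stress by direct double loop
oracle_stress <- function(delta, coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      s <- s + (unclass(delta)[i, j] - dij)^2
    }
  }
  s
}

# Guttman update as an explicit dense B-matrix product
oracle_guttman <- function(delta, coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        dij <- max(sqrt(sum((coords[i, ] - coords[j, ])^2)), 1e-10)
        B[i, j] <- -unclass(delta)[i, j] / dij
      }
    }
  }
  for (i in seq_len(n)) B[i, i] <- -sum(B[i, -i])
  (B %*% coords) / n
}

# ARI by direct enumeration of all item pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      s_a <- s_a + same_a
      s_b <- s_b + same_b
      s_both <- s_both + (same_a && same_b)
    }
  }
  pairs <- n * (n - 1) / 2
  expected <- s_a * s_b / pairs
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_both - expected) / (max_index - expected)
}

# Procrustes residual via the closed form 1 - (trace/n)^2 on unit-RMS
# normalized configurations (no residual matrix is formed)
oracle_procrustes_rmsd <- function(x, y) {
  xc <- scale(as.matrix(x), scale = FALSE)
  yc <- scale(as.matrix(y), scale = FALSE)
  n <- nrow(xc)
  xn <- xc / sqrt(sum(xc^2) / n)
  yn <- yc / sqrt(sum(yc^2) / n)
  tr <- sum(svd(crossprod(yn, xn))$d)
  sqrt(max(0, 1 - (tr / n)^2))
}

# optimal C=2 medoid cost by brute force over all medoid pairs
oracle_best_medoid_cost <- function(delta) {
  dm <- unclass(delta)
  n <- nrow(dm)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      best <- min(best, sum(pmin(dm[, i], dm[, j])))
    }
  }
  best
}

make_records <- function(residues, ids = paste0("r", seq_along(residues))) {
  tibble::tibble(id = ids, residues = residues, truth_label = NA_integer_)
}

# A read set of exactly n_total unique sequences, balanced across families:
# the generator is run with spare members, exact duplicates are stripped,
# and the first n_total/C unique members of each family are kept. Used
# where an exact alignment-count contract is stated over unique reads.
fixture_reads <- function(n_families, n_total, seed,
                          substitution_rate = 0.02, indel_rate = 0.005) {
  per <- ceiling(n_total / n_families * 1.2) + 2
  recs <- generate_families(n_families = n_families,
                            members_per_family = per,
                            substitution_rate = substitution_rate,
                            indel_rate = indel_rate, seed = seed)
  uniq <- deduplicate(recs)
  keep <- unlist(lapply(split(seq_len(nrow(uniq)), uniq$truth_label),
                        utils::head, n_total / n_families))
  out <- uniq[sort(keep), ]
  attr(out, "duplicate_map") <- NULL
  stopifnot(nrow(out) == n_total,
            nrow(deduplicate(out)) == n_total)
  out
}

# per-point residuals between configurations after the same similarity
# superimposition procrustes_compare() uses (unit-RMS normalization of
# both, then optimal rotation/reflection/scale)
procrustes_pointwise_error <- function(ref, cfg) {
  xc <- scale(as.matrix(ref), scale = FALSE)
  yc <- scale(as.matrix(cfg), scale = FALSE)
  n <- nrow(xc)
  xn <- xc / sqrt(sum(xc^2) / n)
  yn <- yc / sqrt(sum(yc^2) / n)
  sv <- svd(crossprod(yn, xn))
  rot <- sv$u %*% t(sv$v)
  resid <- xn - (sum(sv$d) / n) * (yn %*% rot)
  sqrt(rowSums(resid^2))
}
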