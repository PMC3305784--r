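toy_delta <- function(values, ids = as.character(seq_len(nrow(values)))) {
  dist_matrix(values, ids)
}

test_that("k-medoids separates two well-separated pairs", {
  coords <- c(0, 0.05, 0.9, 0.95)
  d <- abs(outer(coords, coords, "-"))
  cl <- kmedoids_cluster(toy_delta(d), 2)
  expect_equal(cl$labels[1], cl$labels[2], ignore_attr = TRUE)
  expect_equal(cl$labels[3], cl$labels[4], ignore_attr = TRUE)
  expect_false(cl$labels[[1]] == cl$labels[[3]])
  # every medoid belongs to its own cluster
  expect_equal(unname(cl$labels[cl$medoid_indices]), 1:2)
})

test_that("C = n puts every point in its own cluster at zero cost", {
  recs <- make_records(c("ACGT", "AGGT", "TTAA", "CCCC"))
  delta <- build_distance_matrix(recs)
  cl <- kmedoids_cluster(delta, 4)
  expect_equal(unname(cl$labels), 1:4)
  expect_equal(cl$total_cost, 0)
})

test_that("PAM attains the exhaustive-search optimum on a small instance", {
  recs <- generate_families(n_families = 2, members_per_family = 4, seed = 40)
  delta <- build_distance_matrix(recs)
  cl <- kmedoids_cluster(delta, 2)
  expect_equal(cl$total_cost, oracle_best_medoid_cost(delta))
})

test_that("cluster count out of range is rejected", {
  recs <- make_records(c("ACGT", "AGGT", "TTAA"))
  delta <- build_distance_matrix(recs)
  expect_error(kmedoids_cluster(delta, 1), class = "seqmds_validation_error")
  expect_error(kmedoids_cluster(delta, 4), class = "seqmds_validation_error")
})

test_that("label propagation keeps in-sample labels and uses nearest medoid", {
  recs <- generate_families(n_families = 2, members_per_family = 5, seed = 41)
  delta <- build_distance_matrix(recs)
  fit <- run_smacof(delta)
  cl <- kmedoids_cluster(delta, 2)

  # zero out-of-sample points: identity
  expect_identical(assign_interpolated_labels(cl, fit$embedding, fit$embedding),
                   cl$labels)

  # a point coincident with a medoid takes that medoid's label
  med <- cl$medoid_indices[1]
  full <- embedding(rbind(unclass(fit$embedding),
                          extra = unclass(fit$embedding)[med, ]),
                    c(rownames(fit$embedding), "extra"))
  lab <- assign_interpolated_labels(cl, fit$embedding, full)
  expect_equal(lab[["extra"]], cl$labels[[med]])
  expect_identical(lab[rownames(fit$embedding)], cl$labels)
})

test_that("out-of-sample reads recover their true family labels", {
  recs <- generate_families(n_families = 3, members_per_family = 40, seed = 42)
  sp <- split_sample(nrow(recs), 60, seed = 43)
  ins <- recs[sp$in_sample, ]
  outs <- recs[sp$out_of_sample, ]
  delta <- build_distance_matrix(ins)
  fit <- run_smacof(delta)
  cl <- kmedoids_cluster(delta, 3)
  full <- run_interpolation(fit$embedding, ins, outs)
  labels <- assign_interpolated_labels(cl, fit$embedding, full)

  out_labels <- labels[outs$id]
  # map each cluster to its majority true family among in-sample reads
  mapping <- vapply(1:3, function(cluster) {
    as.integer(names(which.max(table(
      ins$truth_label[cl$labels == cluster]
    ))))
  }, integer(1))
  accuracy <- mean(mapping[out_labels] == outs$truth_label)
  expect_gte(accuracy, 0.9)
})

test_that("ARI is 1 for identical partitions however labeled", {
  a <- c(0, 0, 1, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(5, 5, 9, 9, 7, 7)), 1)
})

test_that("ARI equals the pair-enumeration oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 0, 1)),
               oracle_ari(c(0, 0, 1, 1), c(0, 0, 0, 1)))
  withr::local_seed(44)
  for (rep in 1:10) {
    a <- sample(0:3, 20, replace = TRUE)
    b <- sample(0:3, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b))
  }
})

test_that("ARI of independent random labelings is near zero on average", {
  withr::local_seed(45)
  vals <- replicate(100, {
    a <- sample(0:4, 60, replace = TRUE)
    b <- sample(0:4, 60, replace = TRUE)
    adjusted_rand_index(a, b)
  })
  expect_lt(abs(mean(vals)), 0.05)
  # a permutation of the items leaves agreement perfect
  a <- sample(0:4, 60, replace = TRUE)
  perm <- sample(60)
  expect_equal(adjusted_rand_index(a[perm], a[perm]), 1)
})

test_that("ARI validates input lengths", {
  expect_error(adjusted_rand_index(1:3, 1:4), class = "seqmds_validation_error")
  expect_error(adjusted_rand_index(1, 1), class = "seqmds_validation_error")
})

test_that("Procrustes is exact under similarity transforms", {
  withr::local_seed(46)
  x <- matrix(rnorm(30), 10, 3)
  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  refl <- diag(c(1, 1, -1))
  y <- 2.5 * x %*% rot %*% refl + matrix(rep(c(1, -2, 3), each = 10), 10, 3)
  rep_xy <- procrustes_compare(x, y)
  expect_lt(rep_xy$rmsd, 1e-8)

  same <- procrustes_compare(x, x)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$scale, 1, tolerance = 1e-12)
})

test_that("Procrustes rmsd matches the closed-form oracle and is symmetric", {
  x <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  y <- x
  y[2, ] <- y[2, ] + c(0.1, 0)
  expect_equal(procrustes_compare(x, y)$rmsd, oracle_procrustes_rmsd(x, y),
               tolerance = 1e-12)
  withr::local_seed(47)
  for (rep in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    b <- matrix(rnorm(24), 8, 3)
    expect_equal(procrustes_compare(a, b)$rmsd, procrustes_compare(b, a)$rmsd,
                 tolerance = 1e-12)
    expect_equal(procrustes_compare(a, b)$rmsd, oracle_procrustes_rmsd(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Procrustes agrees with an established implementation", {
  skip_if_not_installed("vegan")
  withr::local_seed(48)
  x <- matrix(rnorm(36), 12, 3)
  y <- matrix(rnorm(36), 12, 3)
  ref <- vegan::procrustes(x, y, symmetric = TRUE)
  # vegan's symmetric m12^2 equals our squared rmsd (both are the residual
  # between configurations normalized to equal size)
  expect_equal(procrustes_compare(x, y)$rmsd, sqrt(ref$ss),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Procrustes rejects misaligned ids", {
  x <- embedding(matrix(rnorm(9), 3, 3), c("a", "b", "c"))
  y <- embedding(matrix(rnorm(9), 3, 3), c("b", "a", "c"))
  expect_error(procrustes_compare(x, y), class = "seqmds_validation_error")
})
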