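test_that("anchor distances are zero for an identical query and count M alignments", {
  recs <- generate_families(n_families = 2, members_per_family = 5, seed = 20)
  led <- cost_ledger()
  d <- anchor_distances(recs$residues[3], recs, ledger = led)
  expect_equal(led$nw_alignments, nrow(recs))
  expect_equal(unname(d[3]), 0)
  expect_named(d, recs$id)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("select_anchors returns the k smallest, ties to the lower index", {
  expect_equal(sort(select_anchors(c(0.5, 0.1, 0.3), 2)), c(2, 3))
  expect_equal(sort(select_anchors(c(0.5, 0.1, 0.3), 3)), 1:3)
  expect_equal(select_anchors(c(0.2, 0.1, 0.2, 0.05), 3), c(4, 2, 1))
  expect_error(select_anchors(c(0.1, 0.2), 3), class = "seqmds_validation_error")

  withr::local_seed(21)
  d <- runif(100)
  expect_equal(select_anchors(d, 7), order(d)[1:7])
})

test_that("a duplicate query lands exactly on its anchor", {
  p <- matrix(c(1, 2, 3), 1, 3)
  pt <- interpolate_point(0, p)
  expect_identical(pt$coords, c(1, 2, 3))
  expect_equal(pt$n_iterations, 0L)
})

test_that("the symmetric two-anchor case converges to the bisector point", {
  anchors <- rbind(c(0, 0, 0), c(1, 0, 0))
  pt <- interpolate_point(c(0.5, 0.5), anchors,
                          interp_params(tolerance = 1e-14,
                                        max_iterations = 1000))
  expect_lt(pt$point_stress, 1e-8)
  expect_equal(pt$coords[1], 0.5, tolerance = 1e-6)
  d <- sqrt(colSums((t(anchors) - pt$coords)^2))
  expect_equal(unname(d), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("per-point stress is nonincreasing and ledger counts iterations", {
  withr::local_seed(22)
  led <- cost_ledger()
  for (rep in 1:10) {
    anchors <- matrix(rnorm(30), 10, 3)
    deltas <- runif(10, 0.1, 1)
    pt <- interpolate_point(deltas, anchors, ledger = led)
    expect_true(all(diff(pt$stress_trace) <= 1e-12))
  }
  expect_gt(led$majorization_iterations, 0)
})

test_that("an embeddable out-of-sample point is recovered to 1e-3", {
  withr::local_seed(23)
  fix <- generate_geometric(n = 60, n_blobs = 3, seed = 24)
  anchors_idx <- 1:59
  true_all <- unclass(fix$true_coords)
  query_true <- true_all[60, ]
  deltas <- sqrt(colSums((t(true_all[anchors_idx, ]) - query_true)^2))
  pt <- interpolate_point(deltas, true_all[anchors_idx, ],
                          interp_params(k_neighbors = 59,
                                        tolerance = 1e-14,
                                        max_iterations = 2000))
  expect_lt(sqrt(sum((pt$coords - query_true)^2)), 1e-3)
})

test_that("nonfinite interpolation input is rejected", {
  expect_error(interpolate_point(c(NA, 0.5), matrix(0, 2, 3)),
               class = "seqmds_validation_error")
  expect_error(interpolate_point(c(0.1, 0.5), matrix(c(Inf, rep(0, 5)), 2, 3)),
               class = "seqmds_validation_error")
})

test_that("run_interpolation with no out-of-sample points is the identity", {
  recs <- generate_families(n_families = 2, members_per_family = 4, seed = 25)
  fit <- run_smacof(build_distance_matrix(recs))
  out <- run_interpolation(fit$embedding, recs, recs[0, ])
  expect_identical(out, fit$embedding)
})

test_that("an out-of-sample duplicate of an in-sample read is placed on it", {
  recs <- generate_families(n_families = 2, members_per_family = 5, seed = 26)
  fit <- run_smacof(build_distance_matrix(recs))
  dup <- tibble::tibble(id = "dup1", residues = recs$residues[4],
                        truth_label = NA_integer_)
  out <- run_interpolation(fit$embedding, recs, dup)
  expect_equal(unclass(out)["dup1", ], unclass(fit$embedding)[4, ],
               ignore_attr = TRUE)
})

test_that("interpolative cost is exactly M(M-1)/2 + (N-M)*M", {
  recs <- generate_families(n_families = 4, members_per_family = 50,
                            seed = 27)
  sp <- split_sample(200, 50, seed = 28)
  led <- cost_ledger()
  ins <- recs[sp$in_sample, ]
  outs <- recs[sp$out_of_sample, ]
  delta <- build_distance_matrix(ins, ledger = led)
  fit <- run_smacof(delta, ledger = led)
  run_interpolation(fit$embedding, ins, outs, ledger = led)
  expect_identical(led$nw_alignments, 50 * 49 / 2 + 150 * 50)
  expect_identical(led$nw_alignments, 8725)
})

test_that("processing order, chunking and workers never change coordinates", {
  recs <- generate_families(n_families = 3, members_per_family = 10, seed = 29)
  sp <- split_sample(30, 12, seed = 30)
  ins <- recs[sp$in_sample, ]
  outs <- recs[sp$out_of_sample, ]
  fit <- run_smacof(build_distance_matrix(ins))
  ref <- run_interpolation(fit$embedding, ins, outs)

  perm <- withr::with_seed(31, sample(nrow(outs)))
  permuted <- run_interpolation(fit$embedding, ins, outs[perm, ])
  expect_identical(unclass(permuted)[rownames(ref), ], unclass(ref),
                   ignore_attr = TRUE)
  expect_identical(run_interpolation(fit$embedding, ins, outs, block_size = 3),
                   ref)
  expect_identical(run_interpolation(fit$embedding, ins, outs, workers = 4),
                   ref)
  # in-sample coordinates are never touched
  expect_identical(unclass(ref)[seq_len(nrow(ins)), , drop = FALSE],
                   unclass(fit$embedding)[, , drop = FALSE])
})

test_that("id collisions between sets are rejected", {
  recs <- generate_families(n_families = 2, members_per_family = 4, seed = 32)
  fit <- run_smacof(build_distance_matrix(recs))
  expect_error(run_interpolation(fit$embedding, recs, recs[2, ]),
               class = "seqmds_validation_error")
})

test_that("interpolated geometry degrades gracefully versus full MDS", {
  fix <- generate_geometric(n = 200, n_blobs = 4, seed = 33)
  full_fit <- run_smacof(fix$delta, mds_params(tolerance = 1e-10,
                                               max_iterations = 1000))
  full_rmsd <- procrustes_compare(full_fit$embedding, fix$true_coords)$rmsd

  sp <- split_sample(200, 100, seed = 34)
  idx_in <- sp$in_sample
  idx_out <- sp$out_of_sample
  sub <- dist_matrix(unclass(fix$delta)[idx_in, idx_in],
                     rownames(fix$delta)[idx_in])
  in_fit <- run_smacof(sub, mds_params(tolerance = 1e-10,
                                       max_iterations = 1000))
  in_coords <- unclass(in_fit$embedding)
  combined <- matrix(NA_real_, 200, 3)
  combined[idx_in, ] <- in_coords
  ip <- interp_params(k_neighbors = 10, tolerance = 1e-12,
                      max_iterations = 500)
  for (i in idx_out) {
    d_all <- unclass(fix$delta)[i, idx_in]
    sel <- select_anchors(d_all, 10)
    combined[i, ] <- interpolate_point(d_all[sel],
                                       in_coords[sel, , drop = FALSE],
                                       ip)$coords
  }
  interp_emb <- embedding(combined, rownames(fix$delta))
  interp_rmsd <- procrustes_compare(interp_emb, fix$true_coords)$rmsd
  expect_lt(interp_rmsd, max(5 * full_rmsd, 1e-6))
})
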