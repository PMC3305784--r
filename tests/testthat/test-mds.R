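geom_delta <- function(coords, ids = NULL) {
  d <- as.matrix(dist(coords))
  dist_matrix(d / max(d), ids %||% as.character(seq_len(nrow(coords))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("stress is zero for a self-consistent configuration", {
  withr::local_seed(1)
  coords <- matrix(rnorm(15), 5, 3)
  d <- as.matrix(dist(coords))
  delta <- dist_matrix(d / max(d))
  expect_equal(stress(delta, coords / max(d)), 0, tolerance = 1e-20)
})

test_that("stress matches its arithmetic definition", {
  # two points at target 1 embedded 2 apart: (1 - 2)^2 = 1
  delta <- dist_matrix(matrix(c(0, 1, 1, 0), 2, 2))
  x <- matrix(c(0, 2, 0, 0, 0, 0), 2, 3)
  expect_equal(stress(delta, x), 1)
})

test_that("stress equals the double-loop oracle on random instances", {
  withr::local_seed(12)
  for (rep in 1:5) {
    coords <- matrix(rnorm(18), 6, 3)
    target <- matrix(runif(36), 6, 6)
    target <- (target + t(target)) / 2
    target <- target / max(target)
    diag(target) <- 0
    delta <- dist_matrix(target)
    expect_equal(stress(delta, coords), oracle_stress(delta, coords))
  }
})

test_that("stress is translation invariant", {
  withr::local_seed(2)
  coords <- matrix(rnorm(24), 8, 3)
  delta <- geom_delta(matrix(rnorm(24), 8, 3))
  shifted <- sweep(coords, 2, c(3.5, -1, 100), "+")
  expect_equal(stress(delta, coords), stress(delta, shifted))
})

test_that("the Guttman step fixes a zero-stress configuration up to translation", {
  withr::local_seed(3)
  coords <- matrix(rnorm(15), 5, 3)
  d <- as.matrix(dist(coords))
  delta <- dist_matrix(d / max(d))
  x <- coords / max(d)
  x2 <- guttman_step(delta, x)
  shift <- sweep(unclass(x2) - x, 2, colMeans(unclass(x2) - x))
  expect_lt(max(abs(shift)), 1e-12)
})

test_that("the Guttman step equals an explicit B-matrix product and lowers stress", {
  withr::local_seed(4)
  for (rep in 1:5) {
    coords <- matrix(rnorm(12), 4, 3)
    delta <- geom_delta(matrix(rnorm(12), 4, 3))
    stepped <- guttman_step(delta, coords)
    expect_equal(unclass(stepped), oracle_guttman(delta, coords),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_lte(stress(delta, stepped), stress(delta, coords))
  }
})

test_that("SMACOF recovers an exactly embeddable configuration", {
  withr::local_seed(5)
  coords <- matrix(rnorm(150), 50, 3)
  delta <- geom_delta(coords)
  fit <- run_smacof(delta, mds_params(tolerance = 1e-12,
                                      max_iterations = 1000, seed = 1))
  expect_lt(fit$normalized_stress, 1e-4)
})

test_that("two points embed at exactly their target distance", {
  delta <- dist_matrix(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  fit <- run_smacof(delta, mds_params(tolerance = 1e-14, seed = 2))
  expect_equal(dist(unclass(fit$embedding))[1], 0.5, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("the stress trace is nonincreasing, from either initialization", {
  recs <- generate_families(n_families = 3, members_per_family = 6, seed = 10)
  delta <- build_distance_matrix(recs)
  for (init in c("torgerson", "random")) {
    fit <- run_smacof(delta, mds_params(seed = 3, init = init))
    expect_true(all(diff(fit$stress_trace) <= 1e-12))
  }
})

test_that("SMACOF is deterministic for a fixed seed and counts iterations", {
  recs <- generate_families(n_families = 2, members_per_family = 6, seed = 11)
  delta <- build_distance_matrix(recs)
  led <- cost_ledger()
  p <- mds_params(seed = 9, init = "random")
  a <- run_smacof(delta, p, led)
  b <- run_smacof(delta, p)
  expect_identical(a$embedding, b$embedding)
  expect_identical(a$stress_trace, b$stress_trace)
  expect_equal(led$smacof_iterations, a$n_iterations)
  # a different random init gives a different trajectory
  c <- run_smacof(delta, mds_params(seed = 10, init = "random"))
  expect_false(identical(a$stress_trace, c$stress_trace))
})

test_that("degenerate all-zero dissimilarities are rejected", {
  delta <- dist_matrix(matrix(0, 3, 3))
  expect_error(run_smacof(delta), class = "seqmds_degenerate_error")
})
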