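test_that("init_centers draws within the global range, deterministically", {
  X <- matrix(c(0, 3, 9, 4, 2, 7), nrow = 2)
  c1 <- init_centers(X, 4, seed = 11)
  expect_equal(dim(c1), c(4, 3))
  expect_true(all(c1 >= 0 & c1 <= 9))
  expect_identical(c1, init_centers(X, 4, seed = 11))
  expect_false(identical(c1, init_centers(X, 4, seed = 12)))
  # degenerate constant matrix: centers exactly the constant
  expect_equal(init_centers(matrix(5, 3, 2), 2, seed = 1), matrix(5, 2, 2))
  expect_error(init_centers(X, 0), "k must be")
})

test_that("assignment minimizes summed pointwise distance with low-index ties", {
  X <- rbind(c(0, 0), c(10, 10))
  ctr <- rbind(c(0, 0), c(10, 10))
  a <- assign_clusters(X, ctr)
  expect_equal(a$assignments, c(1L, 2L))
  expect_equal(a$total_distance, 0)

  one <- assign_clusters(X, rbind(c(1, 1)))
  expect_equal(one$assignments, c(1L, 1L))
  expect_equal(one$total_distance, (1 + 1) + (81 + 81))

  tie <- assign_clusters(rbind(c(5, 5)), ctr)
  expect_equal(tie$assignments, 1L) # equidistant -> lowest index

  abs_a <- assign_clusters(rbind(c(0, 4)), rbind(c(1, 1), c(0, 0)),
                           distance = "absolute")
  expect_equal(abs_a$total_distance, 4) # |0-1|+|4-1| = 4 for center 1
  expect_equal(abs_a$assignments, 1L)   # squared would prefer center 2
})

test_that("update_centers takes positionwise means and reseeds empty clusters", {
  X <- rbind(c(0, 0), c(2, 2), c(9, 9))
  upd <- update_centers(X, c(1L, 1L, 2L), 2)
  expect_equal(upd$centers, rbind(c(1, 1), c(9, 9)))

  # singleton cluster keeps its one member
  upd <- update_centers(X, c(1L, 2L, 3L), 3)
  expect_equal(upd$centers, X)

  # empty cluster 2 grabs the row farthest from its assigned center
  X2 <- rbind(c(0, 0), c(0, 0), c(9, 9))
  upd <- update_centers(X2, c(1L, 1L, 1L), 2)
  expect_equal(upd$centers[2, ], c(9, 9))
  expect_equal(upd$assignments, c(1L, 1L, 2L))
})

test_that("run_kmeans converges with a monotone objective", {
  X <- rbind(c(0, 0), c(1, 1), c(100, 100), c(101, 101))
  m <- run_kmeans(X, 2, seed = 4)
  expect_true(m$converged)
  expect_equal(m$assignments[1], m$assignments[2])
  expect_equal(m$assignments[3], m$assignments[4])
  expect_false(m$assignments[1] == m$assignments[3])
  expect_true(all(diff(m$history) <= 1e-9))
  # recomputed objective matches the stored one
  d <- assign_clusters(X, m$centers)
  expect_equal(d$total_distance, m$total_distance)
  # centers are the means of their members
  for (j in 1:2) {
    expect_equal(m$centers[j, ],
                 colMeans(X[m$assignments == j, , drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("k = 1 has the closed-form solution; identical rows give zero", {
  set.seed(8)
  X <- matrix(runif(40), 8, 5)
  m <- run_kmeans(X, 1)
  expect_equal(m$centers[1, ], colMeans(X))
  expect_equal(m$total_distance,
               sum(sweep(X, 2, colMeans(X), "-")^2))

  same <- matrix(3, 6, 4)
  m2 <- run_kmeans(same, 3, seed = 2)
  expect_equal(m2$total_distance, 0)
  expect_error(run_kmeans(X, 9), "exceeds")
})

test_that("separated groups reach the brute-force optimum with restarts", {
  set.seed(21)
  X <- rbind(matrix(runif(6, 0, 2), 3, 2),
             matrix(runif(6, 98, 102), 3, 2))
  opt <- oracle_best_bipartition(X)
  best <- min(vapply(1:50, function(r) {
    run_kmeans(X, 2, seed = r)$total_distance
  }, numeric(1)))
  expect_equal(best, opt, tolerance = 1e-9)
})

test_that("stopping rule selects k from an objective sequence", {
  expect_equal(choose_k_from_objectives(c(100, 50, 45), 0.20), 2L)
  expect_equal(choose_k_from_objectives(c(0), 0.20), 1L)    # degenerate
  expect_equal(choose_k_from_objectives(c(100, 79), 0.20), 2L)
  expect_equal(choose_k_from_objectives(c(100, 80), 0.20), 1L) # boundary
  expect_equal(choose_k_from_objectives(c(100, 10, 0), 0.20), 3L)
})

test_that("select_k returns the pre-drop model and a consecutive trace", {
  # two tight groups in 10 dimensions: splitting either further reduces the
  # objective by far less than 20%, so the elbow rule stops at k = 2
  set.seed(5)
  X <- rbind(matrix(rnorm(100, 0, 0.5), 10, 10),
             matrix(rnorm(100, 30, 0.5), 10, 10))
  sel <- select_k(X, seed = 9, restarts = 3)
  expect_equal(sel$model$k, 2L)
  expect_equal(sel$trace$k, seq_len(nrow(sel$trace)))
  expect_true(all(diff(sel$trace$total_distance) <= 1e-9))
  expect_true(is.na(sel$trace$rel_improvement[1]))

  # identical rows: D(1) = 0 -> k = 1 immediately
  sel0 <- select_k(matrix(2, 5, 3), seed = 1)
  expect_equal(sel0$model$k, 1L)
  expect_equal(nrow(sel0$trace), 1L)

  # k_max cap fires with a warning on structure-rich data
  expect_warning(selc <- select_k(X, seed = 9, k_max = 1L), "k_max")
  expect_equal(selc$model$k, 1L)
})

test_that("permuting rows permutes assignments identically", {
  set.seed(31)
  X <- rbind(matrix(runif(30, 0, 1), 15, 2),
             matrix(runif(30, 50, 51), 15, 2))
  rownames(X) <- sprintf("g%02d", 1:30)
  perm <- sample(30)
  Xp <- X[perm, ]
  # same seed protocol after sorting rows by id
  m1 <- run_kmeans(X[order(rownames(X)), ], 2, seed = 77)
  m2 <- run_kmeans(Xp[order(rownames(Xp)), ], 2, seed = 77)
  expect_identical(m1$assignments, m2$assignments)
})

test_that("random tiny instances: restarts reach the optimum, never below", {
  set.seed(2024)
  n_instances <- 40
  hits <- 0
  for (i in seq_len(n_instances)) {
    n <- sample(2:8, 1)
    L <- sample(1:4, 1)
    X <- matrix(runif(n * L, 0, 10), n, L)
    opt <- oracle_best_bipartition(X)
    best <- best_of_restarts_objective(X, 50, base_seed = i)
    expect_gte(best, opt - 1e-9)
    if (best <= opt + 1e-6) hits <- hits + 1
  }
  expect_gte(hits / n_instances, 0.95)
})
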