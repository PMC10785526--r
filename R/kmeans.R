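# K-means on metagene vectors with automatic selection of k.
#
# The variant implemented here initializes every center value uniformly at
# random within the global range of the data, assigns each feature to the
# center minimizing the summed pointwise distance, recomputes centers as
# positionwise means, and iterates until assignments stabilize. k is grown
# from 1 upward until the relative drop in total distance falls to or below
# a threshold (default 20%), at which point the previous k is kept.

pointwise_distance_matrix <- function(X, centers,
                                      distance = c("squared", "absolute")) {
  distance <- match.arg(distance)
  k <- nrow(centers)
  if (distance == "squared") {
    # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, computed in one BLAS call
    d <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, nrow(X)), rowSums(centers^2))
    d[d < 0] <- 0 # clamp tiny negative round-off
    d
  } else {
    d <- matrix(0, nrow(X), k)
    for (j in seq_len(k)) {
      d[, j] <- rowSums(abs(sweep(X, 2L, centers[j, ], "-")))
    }
    d
  }
}

#' Initialize k cluster centers uniformly within the data range
#'
#' Every center value is drawn independently and uniformly from
#' `[min(matrix), max(matrix)]` — one global range, not per-position.
#' Deterministic given `seed`.
#'
#' @param matrix numeric feature matrix (n x L).
#' @param k number of centers, `>= 1`.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a `k x L` numeric matrix.
#' @export
init_centers <- function(matrix, k, seed = NULL) {
  if (k < 1L) stop("k must be >= 1")
  rng <- range(matrix)
  with_seed(seed, {
    matrix(stats::runif(k * ncol(matrix), min = rng[1], max = rng[2]),
           nrow = k)
  })
}

#' Assign each row to its nearest center
#'
#' The distance between a row and a center is the sum over positions of the
#' pointwise distance (squared difference by default, absolute difference
#' optionally). Ties are broken toward the lowest center index.
#'
#' @param matrix numeric feature matrix (n x L).
#' @param centers `k x L` center matrix.
#' @param distance `"squared"` (default) or `"absolute"`.
#' @return list with `assignments` (integer vector in `1..k`),
#'   `total_distance` (sum over rows of the distance to the assigned
#'   center) and `point_distance` (per-row distances).
#' @export
assign_clusters <- function(matrix, centers,
                            distance = c("squared", "absolute")) {
  d <- pointwise_distance_matrix(matrix, centers, distance)
  a <- max.col(-d, ties.method = "first")
  pd <- d[cbind(seq_len(nrow(d)), a)]
  list(assignments = a, total_distance = sum(pd), point_distance = pd)
}

#' Recompute centers as positionwise means of their members
#'
#' Each non-empty cluster's center becomes the positionwise arithmetic mean
#' of its member rows. An empty cluster is reseeded deterministically to
#' the single row farthest from its currently assigned center (that row is
#' moved into the empty cluster); when fewer rows than clusters remain the
#' leftover centers are redrawn uniformly within the data range.
#'
#' @param matrix numeric feature matrix.
#' @param assignments integer vector in `1..k`.
#' @param k number of clusters.
#' @param distance distance mode used for the farthest-row rule.
#' @return list with updated `centers` (k x L) and possibly adjusted
#'   `assignments`.
#' @export
update_centers <- function(matrix, assignments, k,
                           distance = c("squared", "absolute")) {
  distance <- match.arg(distance)
  L <- ncol(matrix)
  centers <- matrix(NA_real_, k, L)
  for (j in seq_len(k)) {
    members <- assignments == j
    if (any(members)) {
      centers[j, ] <- colMeans(matrix[members, , drop = FALSE])
    }
  }
  empty <- which(is.na(centers[, 1L]))
  for (j in empty) {
    filled <- which(!is.na(centers[, 1L]))
    if (length(filled) == 0L || nrow(matrix) < k) {
      centers[j, ] <- init_centers(matrix, 1L)
      next
    }
    d <- pointwise_distance_matrix(matrix, centers[filled, , drop = FALSE],
                                   distance)
    cur <- d[cbind(seq_len(nrow(matrix)), match(assignments, filled))]
    far <- which.max(cur)
    centers[j, ] <- matrix[far, ]
    assignments[far] <- j
  }
  list(centers = centers, assignments = assignments)
}

#' Run k-means to convergence for a fixed k
#'
#' Alternates [assign_clusters()] and [update_centers()] until assignments
#' are unchanged between consecutive iterations or `max_iter` is reached.
#' With the default squared pointwise distance the total distance is
#' non-increasing across iterations (mean centers are optimal for squared
#' distance), so convergence is guaranteed.
#'
#' @param matrix numeric feature matrix (n x L).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed optional integer seed for the random initialization.
#' @param max_iter iteration cap; default 300.
#' @param distance `"squared"` (default) or `"absolute"`.
#' @param centers optional initial `k x L` centers (overrides the random
#'   initialization; used for warm starts).
#' @return a `cluster_model` list: `k`, `centers`, `assignments`,
#'   `total_distance`, `iterations`, `converged`, and `history` (the
#'   total distance recorded at every assignment step).
#' @export
run_kmeans <- function(matrix, k, seed = NULL, max_iter = 300L,
                       distance = c("squared", "absolute"), centers = NULL) {
  distance <- match.arg(distance)
  n <- nrow(matrix)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of rows (", n, ")")
  if (is.null(centers)) {
    centers <- init_centers(matrix, k, seed = seed)
  }
  prev <- NULL
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    a <- assign_clusters(matrix, centers, distance)
    history <- c(history, a$total_distance)
    if (identical(a$assignments, prev)) {
      converged <- TRUE
      break
    }
    upd <- update_centers(matrix, a$assignments, k, distance)
    centers <- upd$centers
    prev <- upd$assignments
  }
  final <- assign_clusters(matrix, centers, distance)
  structure(
    list(k = k, centers = centers, assignments = final$assignments,
         total_distance = final$total_distance, iterations = iter,
         converged = converged, history = history),
    class = "cluster_model")
}

# Best-of-restarts wrapper; optionally adds a warm-start candidate
# initialized from supplied centers. Ties keep the earliest candidate.
best_kmeans <- function(matrix, k, seed = NULL, restarts = 5L,
                        max_iter = 300L, distance = "squared",
                        warm_centers = NULL) {
  best <- NULL
  for (r in seq_len(restarts)) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, k, r)
    m <- run_kmeans(matrix, k, seed = s, max_iter = max_iter,
                    distance = distance)
    if (is.null(best) || m$total_distance < best$total_distance) best <- m
  }
  if (!is.null(warm_centers)) {
    m <- run_kmeans(matrix, k, max_iter = max_iter, distance = distance,
                    centers = warm_centers)
    if (m$total_distance < best$total_distance) best <- m
  }
  best
}

#' Apply the elbow-style stopping rule to a sequence of objectives
#'
#' Given total distances `D(1), D(2), ...` for consecutive k starting at 1,
#' returns the selected k: the first k (from 2 up) whose relative
#' improvement `(D(k-1) - D(k)) / D(k-1)` fails to exceed `threshold`
#' selects `k - 1`; a zero objective selects that k immediately; otherwise
#' the largest k tried is selected.
#'
#' @param objectives numeric vector, `objectives[i] = D(i)`.
#' @param threshold relative-improvement threshold in (0, 1); default 0.20.
#' @return the selected k (integer).
#' @export
#' @examples
#' choose_k_from_objectives(c(100, 50, 45)) # 2: 50% then 10% improvement
choose_k_from_objectives <- function(objectives, threshold = 0.20) {
  if (length(objectives) < 1L) stop("need at least D(1)")
  if (objectives[1L] == 0) return(1L)
  for (k in seq_along(objectives)[-1L]) {
    imp <- (objectives[k - 1L] - objectives[k]) / objectives[k - 1L]
    if (imp <= threshold) return(k - 1L)
    if (objectives[k] == 0) return(k)
  }
  length(objectives)
}

#' Cluster with automatic selection of the number of clusters
#'
#' Runs best-of-`restarts` k-means for k = 1, 2, 3, ... and stops at the
#' first k whose relative improvement in total distance is at or below
#' `threshold` (default 20%), returning the model for the previous k. Also
#' stops when the objective reaches zero (returns that k) or at `k_max`
#' (returned with a warning). Every k tried is recorded in the trace.
#'
#' In addition to the random restarts, each k >= 2 evaluates one warm-start
#' candidate built from the previous k's best centers plus the row farthest
#' from its assigned center; this guarantees the objective trace D(k) is
#' non-increasing in k. Set `warm_start = FALSE` (with `restarts = 1`) for
#' the plain single-random-initialization procedure.
#'
#' @param matrix numeric feature matrix (n x L).
#' @param threshold relative-improvement stopping threshold in (0, 1);
#'   default 0.20.
#' @param seed integer seed driving all restarts; default 1337.
#' @param k_max largest k to try; default 10.
#' @param restarts random initializations per k, keeping the lowest
#'   objective; default 5.
#' @param distance `"squared"` (default) or `"absolute"`.
#' @param max_iter per-run iteration cap; default 300.
#' @param warm_start add the warm-start candidate per k? Default `TRUE`.
#' @return list with `model` (the selected `cluster_model`) and `trace`
#'   (data frame with columns `k`, `total_distance`, `rel_improvement`).
#' @export
select_k <- function(matrix, threshold = 0.20, seed = 1337L, k_max = 10L,
                     restarts = 5L, distance = c("squared", "absolute"),
                     max_iter = 300L, warm_start = TRUE) {
  distance <- match.arg(distance)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (k_max < 1L) stop("k_max must be >= 1")

  models <- list()
  D <- numeric(0)
  trace <- data.frame(k = integer(0), total_distance = numeric(0),
                      rel_improvement = numeric(0))
  prev <- NULL
  for (k in seq_len(k_max)) {
    warm <- NULL
    if (warm_start && !is.null(prev)) {
      far <- which.max(assign_clusters(matrix, prev$centers,
                                       distance)$point_distance)
      warm <- rbind(prev$centers, matrix[far, ])
    }
    m <- best_kmeans(matrix, k, seed = seed, restarts = restarts,
                     max_iter = max_iter, distance = distance,
                     warm_centers = warm)
    D[k] <- m$total_distance
    models[[k]] <- m
    imp <- if (k == 1L) NA_real_ else (D[k - 1L] - D[k]) / D[k - 1L]
    trace <- rbind(trace, data.frame(k = k, total_distance = D[k],
                                     rel_improvement = imp))
    sel <- choose_k_from_objectives(D, threshold)
    if (sel < k || D[k] == 0) {
      return(list(model = models[[sel]], trace = trace))
    }
    prev <- m
  }
  warning("k_max (", k_max, ") reached before the stopping rule fired")
  list(model = models[[k_max]], trace = trace)
}
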