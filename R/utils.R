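# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#' With `seed = NULL` the code runs against the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent random partitions. Used to score cluster recovery against
#' planted labels in simulations.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric scalar in (-1, 1].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: same partition
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label vectors must have equal length")
  }
  n <- length(a)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) {
    return(1) # both partitions trivial (all-one-cluster or all-singletons)
  }
  (sum_ij - expected) / (max_idx - expected)
}

# stderr logging with a level gate; pipeline stages use this so that stdout
# stays clean for user-facing results.
log_msg <- function(level = c("info", "warn", "debug"), ...) {
  level <- match.arg(level)
  threshold <- getOption("clustagene.log_level", "info")
  ranks <- c(warn = 1L, info = 2L, debug = 3L)
  if (ranks[[level]] <= ranks[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Derive a per-task seed below 2^31 from a base seed and small task indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  out <- as.double(seed)
  for (i in idx) {
    out <- (out * 69069 + as.double(i)) %% 2147483647
  }
  as.integer(out)
}
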