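#' Probabilistic rank-score matrix for one analyte
#'
#' Tallies, over all rank-order signatures recorded for one target gas,
#' how often each sensor spiked at each rank: `P[i, j] = N[i, j] / N`,
#' the probability that sensor `i` spikes at rank `j` (columns are ranks
#' 0..n-1). On complete frames every column sums to one, since each
#' pattern places exactly one sensor at each rank.
#'
#' @param patterns an n x m integer matrix (rows = rank-of-sensor
#'   signatures) or a list of such vectors; all complete permutations.
#' @param analyte optional label stored with the matrix.
#' @return object of class `"rank_score"`: list with `probs` (m x m),
#'   `counts`, `n_patterns`, `analyte`.
#' @export
rank_score_matrix <- function(patterns, analyte = NULL) {
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  if (is.null(dim(patterns)) && length(patterns))
    patterns <- matrix(patterns, nrow = 1L)
  if (is.null(patterns) || nrow(patterns) < 1L)
    stop("at least one rank-order pattern is required", call. = FALSE)
  m <- ncol(patterns)
  for (r in seq_len(nrow(patterns))) .check_rank_order(patterns[r, ], m)
  counts <- matrix(0L, m, m,
                   dimnames = list(sensor = paste0("S", 0:(m - 1L)),
                                   rank = 0:(m - 1L)))
  for (r in seq_len(nrow(patterns))) {
    idx <- cbind(seq_len(m), patterns[r, ] + 1L)
    counts[idx] <- counts[idx] + 1L
  }
  structure(list(probs = counts / nrow(patterns), counts = counts,
                 n_patterns = nrow(patterns), analyte = analyte),
            class = "rank_score")
}

#' @export
print.rank_score <- function(x, digits = 3, ...) {
  cat("Rank-score matrix",
      if (!is.null(x$analyte)) paste0(" [", x$analyte, "]"),
      ": ", x$n_patterns, " patterns, ", nrow(x$probs), " sensors\n",
      sep = "")
  print(round(x$probs, digits))
  invisible(x)
}

#' Reference rank-order signature from a rank-score matrix
#'
#' Collapses the per-gas probability matrix into the single signature
#' used as the learning pattern for that gas: each rank is assigned the
#' sensor most likely to spike there. The default greedy rule processes
#' (sensor, rank) cells in decreasing probability, ties broken by lower
#' rank then lower sensor index, and accepts a cell when both its sensor
#' and rank are still free; the result is always a complete permutation.
#' `method = "optimal"` instead maximises the total assigned probability
#' with an exact linear-assignment solver.
#'
#' @param x a `"rank_score"` object, or a square probability matrix
#'   (rows = sensors, columns = ranks).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return integer permutation: rank of each sensor.
#' @export
reference_signature <- function(x, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  p <- if (inherits(x, "rank_score")) x$probs else as.matrix(x)
  m <- nrow(p)
  if (ncol(p) != m || any(!is.finite(p)) || any(p < 0))
    stop("need a square matrix of non-negative finite scores",
         call. = FALSE)
  if (method == "optimal") {
    cols <- .lsap_min(-p)               # maximise probability
    return(as.integer(cols - 1L))       # rank of sensor i
  }
  sensor_v <- rep(seq_len(m), times = m)
  rank_v <- rep(seq_len(m), each = m)
  prob_v <- as.vector(p)
  ord <- order(-prob_v, rank_v, sensor_v)
  rank_of_sensor <- rep(NA_integer_, m)
  rank_taken <- rep(FALSE, m)
  for (cell in ord) {
    s <- sensor_v[cell]; r <- rank_v[cell]
    if (is.na(rank_of_sensor[s]) && !rank_taken[r]) {
      rank_of_sensor[s] <- r - 1L
      rank_taken[r] <- TRUE
      if (all(rank_taken)) break
    }
  }
  rank_of_sensor
}

# Exact linear assignment (minimisation) via shortest augmenting paths
# (Jonker-Volgenant style, O(n^3)). Returns the assigned column for each
# row. Written here because no assignment solver is available among the
# package's dependencies.
.lsap_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j] = row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    way <- integer(n)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assigned <- integer(n)
  for (j in seq_len(n)) assigned[p[j]] <- j
  assigned
}
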