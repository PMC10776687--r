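#' k-means microstate discretization
#'
#' Discretizes IC-space trajectories into `k` cluster centres: k-means++
#' initialization under a fixed seed followed by Lloyd iterations until the
#' relative inertia change drops below `tol` (or `max_iter` rounds); empty
#' clusters are re-seeded from the point farthest from its centre. The same
#' seed always yields identical assignments.
#'
#' @param data matrix of projected frames, or a list of per-trajectory
#'   matrices (trajectory boundaries are preserved in the output)
#' @param k number of cluster centres (default 500)
#' @param seed integer seed
#' @param max_iter Lloyd iteration cap (default 500)
#' @param tol relative inertia convergence threshold (default 1e-6)
#' @return object of class `discretization`: `centers` (k x d), `dtrajs`
#'   (list of 0-based state index vectors), `inertia`, `seed`
#' @export
discretize <- function(data, k = 500L, seed = NULL, max_iter = 500L,
                       tol = 1e-6) {
  if (!is.list(data) || is.data.frame(data)) data <- list(data)
  mats <- lapply(data, function(x) as.matrix(x))
  lens <- vapply(mats, nrow, 1L)
  X <- do.call(rbind, mats)
  n <- nrow(X)
  if (k > n) stopf("k (%d) exceeds the number of frames (%d)", k, n)

  centers <- with_seed(seed, kmeanspp_init(X, k))
  inertia <- Inf
  for (it in seq_len(max_iter)) {
    asg <- assign_nearest_cpp(X, centers)
    cl <- asg$cluster + 1L
    new_inertia <- sum(asg$dist2)
    counts <- tabulate(cl, nbins = k)
    sums <- rowsum(X, cl)          # rows sorted by cluster id
    present <- sort(unique(cl))
    centers[present, ] <- sums / counts[present]
    for (j in which(counts == 0L))
      centers[j, ] <- X[which.max(asg$dist2), ]
    if (is.finite(inertia) &&
        abs(inertia - new_inertia) <= tol * max(inertia, 1e-300)) {
      inertia <- new_inertia
      break
    }
    inertia <- new_inertia
  }
  asg <- assign_nearest_cpp(X, centers)
  inertia <- sum(asg$dist2)
  splits <- rep(seq_along(lens), lens)
  dtrajs <- split(asg$cluster, splits)
  names(dtrajs) <- names(data) %||% NULL
  structure(list(centers = centers, dtrajs = unname(lapply(dtrajs, as.integer)),
                 projections = mats, inertia = inertia, k = k, seed = seed),
            class = "discretization")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  d <- ncol(X)
  dist2_to <- function(ctr) {
    s <- (X[, 1] - ctr[1])^2
    for (m in seq_len(d - 1L) + 1L) s <- s + (X[, m] - ctr[m])^2
    s
  }
  centers <- matrix(0, k, d)
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- dist2_to(centers[1L, ])
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    # single weighted draw by inverse CDF (sample.int with prob is O(n log n)
    # per call, far too slow for millions of frames)
    i <- if (tot <= 0) sample.int(n, 1L)
    else min(findInterval(runif(1L) * tot, cumsum(d2)) + 1L, n)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, dist2_to(centers[j, ]))
  }
  centers
}

#' @export
print.discretization <- function(x, ...) {
  cat(sprintf("<discretization> k = %d over %d trajectory(ies), inertia = %.4g\n",
              x$k, length(x$dtrajs), x$inertia))
  invisible(x)
}

#' Assign new frames to existing cluster centres
#'
#' @param disc discretization
#' @param data matrix of frames in the same space as the centres
#' @return integer vector of 0-based state indices
#' @export
assign_states <- function(disc, data) {
  as.integer(assign_nearest_cpp(as.matrix(data), disc$centers)$cluster)
}
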