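#' Estimate a Markov state model from discrete trajectories
#'
#' Sliding-window transition counts at the requested lag, restriction to the
#' largest strongly connected set of the count graph, and (by default) the
#' reversible maximum-likelihood transition matrix via the standard
#' self-consistent iteration on the symmetrized sufficient statistics,
#' converged when the largest transition-probability change falls below
#' 1e-10. The stationary distribution is the fixed point of the iteration;
#' with `reversible = FALSE` the counts are simply row-normalized.
#'
#' @param dtrajs list of 0-based integer state sequences (or one vector)
#' @param lag_ns Markov lag time in ns (default 25)
#' @param dt_ns frame spacing in ns (default 0.5, so the default lag is 50
#'   frames); the lag must be a positive multiple of the stride
#' @param reversible detailed-balance-constrained estimate (default TRUE)
#' @param count_mode "sliding" (window moves one frame at a time, default)
#'   or "strided" (independent windows)
#' @return object of class `msm_model`: `T` (row-stochastic), `pi`,
#'   `eigenvalues` (descending), `counts` (full matrix), `active` (0-based
#'   original state labels of the connected set), `lag_ns`, `dt_ns`
#' @export
estimate_msm <- function(dtrajs, lag_ns = 25, dt_ns = 0.5, reversible = TRUE,
                         count_mode = c("sliding", "strided")) {
  count_mode <- match.arg(count_mode)
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  tau <- lag_to_steps(lag_ns, dt_ns)
  K <- max(vapply(dtrajs, function(d) if (length(d)) max(d) else -1L, 1L)) + 1L
  C <- count_transitions(dtrajs, tau, K, count_mode)

  act <- largest_connected_set(C)
  dropped <- setdiff(seq_len(K) - 1L, act)
  if (length(act) < 2L)
    stopf("no connected set with >= 2 states at lag %g ns", lag_ns)
  if (length(dropped))
    warnf("%d state(s) outside the largest connected set dropped: %s",
          length(dropped), paste(utils::head(dropped, 10L), collapse = ", "))
  Ca <- C[act + 1L, act + 1L, drop = FALSE]

  if (reversible) {
    fit <- reversible_mle_cpp(Ca, 1e-10, 1000000L)
    if (!fit$converged)
      warnf("reversible estimator did not reach 1e-10 within the iteration cap")
    T_ <- fit$T
    pi_ <- as.numeric(fit$pi)
    # symmetrized spectral decomposition: real eigenvalues for reversible T
    s <- sqrt(pi_)
    S <- (T_ * outer(s, 1 / s) + t(T_ * outer(s, 1 / s))) / 2
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  } else {
    T_ <- Ca / rowSums(Ca)
    eg <- eigen(t(T_))
    i1 <- which.min(abs(eg$values - 1))
    v <- Re(eg$vectors[, i1])
    pi_ <- v / sum(v)
    ev <- Re(eg$values)[order(-Re(eg$values))]
  }
  structure(list(T = T_, pi = pi_, eigenvalues = ev, counts = C,
                 active = act, lag_ns = lag_ns, dt_ns = dt_ns,
                 reversible = reversible, count_mode = count_mode),
            class = "msm_model")
}

count_transitions <- function(dtrajs, tau, K, count_mode) {
  C <- matrix(0, K, K)
  for (d in dtrajs) {
    n <- length(d)
    if (n <= tau) next
    from <- if (count_mode == "sliding") seq_len(n - tau) else seq(1L, n - tau, by = tau)
    idx <- d[from] * K + d[from + tau] + 1L
    tab <- tabulate(idx, nbins = K * K)
    C <- C + matrix(tab, K, K, byrow = TRUE)
  }
  C
}

# 0-based labels of the largest strongly connected component (ties broken by
# total outgoing counts)
largest_connected_set <- function(C) {
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    wt <- vapply(best, function(b) sum(C[comp$membership == b, , drop = FALSE]), 1.0)
    best <- best[which.max(wt)]
  }
  sort(which(comp$membership == best[1]) - 1L)
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("<msm_model> %d states (of %d), lag %g ns, %s; t2 = %s ns\n",
              length(x$active), nrow(x$counts), x$lag_ns,
              if (x$reversible) "reversible" else "non-reversible",
              if (length(x$eigenvalues) > 1 && x$eigenvalues[2] > 0 && x$eigenvalues[2] < 1)
                sprintf("%.3g", -x$lag_ns / log(x$eigenvalues[2])) else "n/a"))
  invisible(x)
}

#' Implied relaxation timescales across lag times
#'
#' For each candidate lag, estimates an MSM and converts eigenvalues to
#' timescales `t_i(tau) = -tau / log(lambda_i(tau))` (i >= 2). Eigenvalues
#' outside (0, 1) give an undefined (NA) timescale rather than a clamped
#' value. Convergence of `t_i` across lags motivates the production lag.
#'
#' @param dtrajs list of 0-based state sequences
#' @param lags_ns lag times to scan, ns
#' @param n_timescales how many slow processes to report (default 3)
#' @param dt_ns frame spacing, ns
#' @param reversible passed to [estimate_msm()]
#' @param n_boot optional number of trajectory bootstrap replicates for
#'   per-lag standard deviations (0 = none)
#' @param seed seed for the bootstrap resampling
#' @return object of class `its_curve`: data.frame with lag_ns, index,
#'   lambda, its_ns (and its_sd if bootstrapped)
#' @export
implied_timescales <- function(dtrajs, lags_ns, n_timescales = 3L,
                               dt_ns = 0.5, reversible = TRUE, n_boot = 0L,
                               seed = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  maxlen <- max(vapply(dtrajs, length, 1L))
  rows <- list()
  for (lag in lags_ns) {
    if (lag_to_steps(lag, dt_ns) >= maxlen)
      stopf("lag %g ns is not shorter than the longest trajectory", lag)
    m <- estimate_msm(dtrajs, lag_ns = lag, dt_ns = dt_ns,
                      reversible = reversible)
    its <- its_from_model(m, n_timescales)
    if (n_boot > 0L) {
      boots <- with_seed(seed, {
        vapply(seq_len(n_boot), function(b) {
          idx <- sample.int(length(dtrajs), replace = TRUE)
          mb <- try(suppressWarnings(
            estimate_msm(dtrajs[idx], lag_ns = lag, dt_ns = dt_ns,
                         reversible = reversible)), silent = TRUE)
          if (inherits(mb, "try-error")) return(rep(NA_real_, n_timescales))
          its_from_model(mb, n_timescales)$its_ns
        }, numeric(n_timescales))
      })
      its$its_sd <- apply(rbind(boots), 1L, sd, na.rm = TRUE)
    }
    its$lag_ns <- lag
    rows[[length(rows) + 1L]] <- its
  }
  out <- do.call(rbind, rows)
  class(out) <- c("its_curve", "data.frame")
  out
}

its_from_model <- function(m, n_timescales) {
  lam <- m$eigenvalues[seq_len(min(n_timescales, length(m$eigenvalues) - 1L)) + 1L]
  its <- ifelse(lam > 0 & lam < 1, -m$lag_ns / log(lam), NA_real_)
  data.frame(index = seq_along(lam) + 1L, lambda = lam, its_ns = its)
}

#' Chapman-Kolmogorov test
#'
#' Validates Markovianity by comparing the model's prediction
#' `[T(tau)^k]` against MSMs re-estimated directly at lag `k*tau`, on
#' metastable-set self-transition probabilities. Macrostates are defined by
#' the sign structure of the slow right eigenvectors of the estimated
#' transition matrix (two states from the second eigenvector; more states
#' from successive eigenvectors). Bootstrap standard deviations come from
#' resampling whole trajectories with replacement.
#'
#' @param model msm_model estimated from `dtrajs`
#' @param dtrajs the discrete trajectories the model was estimated from
#' @param n_macrostates number of metastable sets (default 2)
#' @param factors lag multiples to test (default 1:5); factors whose lag
#'   reaches the trajectory length are dropped with a warning
#' @param n_boot bootstrap replicates for the estimated side (default 20)
#' @param seed seed for the bootstrap
#' @return object of class `ck_result`: data.frame with macrostate, factor,
#'   predicted, estimated, boot_sd
#' @export
ck_test <- function(model, dtrajs, n_macrostates = 2L, factors = 1:5,
                    n_boot = 20L, seed = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  maxlen <- max(vapply(dtrajs, length, 1L))
  tau_steps <- lag_to_steps(model$lag_ns, model$dt_ns)
  ok <- factors * tau_steps < maxlen
  if (any(!ok))
    warnf("factor(s) %s exceed the trajectory length and were dropped",
          paste(factors[!ok], collapse = ", "))
  factors <- factors[ok]
  sets <- macrostate_sets(model, n_macrostates)

  self_prob <- function(T_, pi_, active, k, set_states) {
    Tk <- matpow(T_, k)
    rows <- which(active %in% set_states)
    if (!length(rows)) return(NA_real_)
    w <- pi_[rows] / sum(pi_[rows])
    sum(w * rowSums(Tk[rows, which(active %in% set_states), drop = FALSE]))
  }
  est_model <- function(dtl, k) {
    suppressWarnings(estimate_msm(dtl, lag_ns = model$lag_ns * k,
                                  dt_ns = model$dt_ns,
                                  reversible = model$reversible))
  }

  rows <- list()
  boot_idx <- with_seed(seed, lapply(seq_len(n_boot), function(b)
    sample.int(length(dtrajs), replace = TRUE)))
  for (k in factors) {
    mk <- if (k == 1L) model else est_model(dtrajs, k)
    for (s in seq_along(sets)) {
      pred <- self_prob(model$T, model$pi, model$active, k, sets[[s]])
      est <- self_prob(mk$T, mk$pi, mk$active, 1L, sets[[s]])
      bvals <- vapply(boot_idx, function(idx) {
        mb <- try(est_model(dtrajs[idx], k), silent = TRUE)
        if (inherits(mb, "try-error")) return(NA_real_)
        self_prob(mb$T, mb$pi, mb$active, 1L, sets[[s]])
      }, 1.0)
      rows[[length(rows) + 1L]] <- data.frame(
        macrostate = s, factor = k, predicted = pred, estimated = est,
        boot_sd = sd(bvals, na.rm = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sets") <- sets
  class(out) <- c("ck_result", "data.frame")
  out
}

# metastable sets from the sign structure of right eigenvectors 2..m
macrostate_sets <- function(model, n_macrostates) {
  if (n_macrostates < 2L) stopf("need >= 2 macrostates")
  s <- sqrt(model$pi)
  Tsym <- (model$T * outer(s, 1 / s) + t(model$T * outer(s, 1 / s))) / 2
  eg <- eigen(Tsym, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)
  n_vec <- min(n_macrostates - 1L, length(model$active) - 1L)
  R <- eg$vectors[, ord[seq_len(n_vec) + 1L], drop = FALSE] / s  # right eigenvectors
  pattern <- apply(R >= 0, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_along(pattern), pattern)
  # keep the n largest groups by stationary weight, merge the rest into the
  # group with the nearest sign pattern
  wt <- vapply(groups, function(g) sum(model$pi[g]), 1.0)
  keep <- order(-wt)[seq_len(min(n_macrostates, length(groups)))]
  sets <- groups[keep]
  if (length(groups) > length(keep)) {
    kept_pat <- names(groups)[keep]
    for (g in setdiff(seq_along(groups), keep)) {
      dist <- vapply(kept_pat, function(p)
        sum(strsplit(p, "")[[1]] != strsplit(names(groups)[g], "")[[1]]), 1.0)
      tgt <- which.min(dist)
      sets[[tgt]] <- c(sets[[tgt]], groups[[g]])
    }
  }
  lapply(sets, function(g) model$active[g])  # 0-based original labels
}

matpow <- function(M, k) {
  out <- diag(nrow(M))
  for (i in seq_len(k)) out <- out %*% M
  out
}
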