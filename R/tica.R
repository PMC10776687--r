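#' Time-lagged independent component analysis
#'
#' Linear projections ordered by slowness: solves the generalized
#' eigenproblem `C(tau) v = lambda C(0) v` with the symmetrized time-lagged
#' covariance `C(tau) = (C_0tau + C_0tau') / 2` accumulated over all
#' trajectories (lagged pairs never straddle trajectory boundaries) and a
#' ridge-regularized instantaneous covariance. The first independent
#' components span the slow occlusion motions onto which every ligand
#' condition is projected for direct comparison; fit the model once on the
#' pooled all-condition dataset.
#'
#' @param tables list of feature_table (or plain matrices with `dt_ns` set)
#' @param lag_ns lag time, ns (default 5)
#' @param dt_ns frame spacing, ns; taken from the tables when NULL
#' @param ridge relative ridge added to C(0): `ridge * trace/d` (default 1e-10)
#' @return object of class `tica_model`: means, eigenvalues (descending),
#'   unit-norm component vectors (sign-fixed), covariances, lag, hash
#' @export
fit_tica <- function(tables, lag_ns = 5, dt_ns = NULL, ridge = 1e-10) {
  if (inherits(tables, "feature_table") || is.matrix(tables))
    tables <- list(tables)
  mats <- lapply(tables, as_design_matrix)
  if (is.null(dt_ns)) {
    strides <- vapply(tables, function(tb)
      if (inherits(tb, "feature_table")) frame_stride(tb) else NA_real_, 1.0)
    dt_ns <- strides[!is.na(strides)][1]
    if (is.na(dt_ns)) stopf("dt_ns must be given for matrix input")
  }
  tau <- lag_to_steps(lag_ns, dt_ns)

  d <- ncol(mats[[1]])
  usable <- vapply(mats, nrow, 1L) > tau
  if (any(!usable))
    warnf("%d trajectory(ies) shorter than the lag were skipped", sum(!usable))
  if (!any(usable)) stopf("no trajectory longer than the lag (%g ns)", lag_ns)
  mats <- mats[usable]

  # pass 1: symmetrized mean over both ends of all lagged pairs
  s <- numeric(d); N <- 0
  for (X in mats) {
    n <- nrow(X)
    i0 <- seq_len(n - tau)
    s <- s + colSums(X[i0, , drop = FALSE]) + colSums(X[i0 + tau, , drop = FALSE])
    N <- N + length(i0)
  }
  mu <- s / (2 * N)
  # pass 2: symmetrized covariances
  C0 <- Ct <- matrix(0, d, d)
  for (X in mats) {
    n <- nrow(X)
    i0 <- seq_len(n - tau)
    A <- sweep(X[i0, , drop = FALSE], 2L, mu)
    B <- sweep(X[i0 + tau, , drop = FALSE], 2L, mu)
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B)
  }
  C0 <- C0 / (2 * N)
  Ct <- (Ct + t(Ct)) / (2 * N)

  C0r <- C0 + diag(ridge * sum(diag(C0)) / d, d)
  U <- chol(C0r)
  Ui <- backsolve(U, diag(d))
  M <- t(Ui) %*% Ct %*% Ui
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- Ui %*% eg$vectors
  V <- apply(V, 2L, function(v) fix_sign(v / sqrt(sum(v^2))))
  model <- structure(list(lag_ns = lag_ns, dt_ns = dt_ns, mean = mu,
                          eigenvalues = eg$values, components = V,
                          C0 = C0, Ctau = Ct,
                          feature_names = colnames(mats[[1]])),
                     class = "tica_model")
  model$hash <- object_hash(list(mu, eg$values, V, lag_ns))
  model
}

lag_to_steps <- function(lag_ns, dt_ns) {
  tau <- lag_ns / dt_ns
  if (abs(tau - round(tau)) > 1e-8 || round(tau) < 1)
    stopf("lag (%g ns) must be a positive multiple of the frame stride (%g ns)",
          lag_ns, dt_ns)
  as.integer(round(tau))
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> lag %g ns, %d features, top eigenvalues: %s\n",
              x$lag_ns, length(x$mean),
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 3L)),
                    collapse = ", ")))
  invisible(x)
}

#' Project data onto independent components
#'
#' @param model tica_model
#' @param data feature_table / matrix / list thereof
#' @param n_components number of ICs to keep (default 2: IC1, IC2)
#' @return matrix of IC scores (or list of matrices for list input)
#' @export
tica_project <- function(model, data, n_components = 2L) {
  one <- function(x) {
    X <- as_design_matrix(x)
    if (ncol(X) != length(model$mean))
      stopf("feature dimension mismatch (%d vs %d)", ncol(X), length(model$mean))
    S <- sweep(X, 2L, model$mean) %*%
      model$components[, seq_len(n_components), drop = FALSE]
    colnames(S) <- paste0("IC", seq_len(n_components))
    S
  }
  if (is.list(data) && !is.data.frame(data)) lapply(data, one) else one(data)
}
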