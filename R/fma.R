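#' Functional mode analysis (partial-least-squares collective mode)
#'
#' Finds the collective mode that maximises covariance with a scalar query
#' (here: the ligand-residue interaction energy). The implementation is
#' PLS1: directions maximising covariance with the query residual are
#' extracted and deflated for `n_components` rounds; the reported mode is
#' the regression-optimal combination of the components (the
#' ensemble-weighted maximally correlated mode). Trajectories longer than
#' `n_frames` are subsampled at equal spacing (first and last frame always
#' included). Validation uses a time-blocked split (first half train,
#' second half test) to respect autocorrelation.
#'
#' @param data matrix (frames x coordinates/features), feature_table, or
#'   list thereof (pooled)
#' @param query numeric query series, one value per frame of `data`
#' @param n_components number of PLS components (default 10)
#' @param n_frames number of equally spaced frames used for fitting
#'   (default 2000)
#' @param validate compute a cross-validated correlation on a held-out
#'   second half (default TRUE)
#' @return object of class `fma_model`: unit `mode` vector, `coef`
#'   (regression vector), `mean`/`query_mean` offsets, `training_correlation`,
#'   `cv_correlation`, `n_components`
#' @export
fit_fma <- function(data, query, n_components = 10L, n_frames = 2000L,
                    validate = TRUE) {
  X <- pool_rows(data)
  y <- as.numeric(query)
  if (length(y) != nrow(X))
    stopf("query length (%d) must match frame count (%d)", length(y), nrow(X))
  if (sd(y) == 0) stopf("query has zero variance")
  idx <- equally_spaced(nrow(X), n_frames)
  X <- X[idx, , drop = FALSE]
  y <- y[idx]

  if (validate) {
    half <- floor(length(y) / 2)
    fit <- pls1(X[seq_len(half), , drop = FALSE], y[seq_len(half)], n_components)
    test_x <- X[(half + 1):length(y), , drop = FALSE]
    test_y <- y[(half + 1):length(y)]
    pred <- sweep(test_x, 2L, fit$mean) %*% fit$coef
    cv_cor <- if (sd(pred) > 0) cor(pred, test_y)[1] else 0
  } else {
    cv_cor <- NA_real_
  }
  fit <- pls1(X, y, n_components)
  pred <- sweep(X, 2L, fit$mean) %*% fit$coef
  train_cor <- cor(pred, y)[1]
  mode <- fix_sign(fit$coef / sqrt(sum(fit$coef^2)))
  structure(list(mode = as.numeric(mode), coef = as.numeric(fit$coef),
                 mean = fit$mean, query_mean = fit$query_mean,
                 training_correlation = train_cor, cv_correlation = cv_cor,
                 n_components = n_components),
            class = "fma_model")
}

# indices of n equally spaced frames, first and last always included
equally_spaced <- function(n_total, n) {
  if (n >= n_total) return(seq_len(n_total))
  unique(round(seq(1, n_total, length.out = n)))
}

# PLS1 (NIPALS) with regression coefficients b = W (P'W)^-1 q
pls1 <- function(X, y, ncomp) {
  mu <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, mu)
  yc <- y - ybar
  p <- ncol(X)
  ncomp <- min(ncomp, p, nrow(X) - 1L)
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  nw1 <- NA_real_
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (is.na(nw1)) nw1 <- nw
    # stop once the query residual is numerically exhausted; keeping
    # degenerate directions would pollute the regression vector
    if (nw < 1e-8 * nw1 || nw == 0) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    pvec <- crossprod(Xc, t_) / tt
    qa <- sum(yc * t_) / tt
    Xc <- Xc - t_ %*% t(pvec)
    yc <- yc - qa * t_
    W[, a] <- w
    P[, a] <- pvec
    q[a] <- qa
  }
  if (ncomp == 0L) stopf("query is orthogonal to the data")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  coef <- W %*% solve(crossprod(P, W), q)
  list(coef = coef, mean = mu, query_mean = ybar)
}

#' @export
print.fma_model <- function(x, ...) {
  cat(sprintf("<fma_model> %d components, training r = %.3f, cv r = %s\n",
              x$n_components, x$training_correlation,
              ifelse(is.na(x$cv_correlation), "NA",
                     sprintf("%.3f", x$cv_correlation))))
  invisible(x)
}

#' Predict the query from coordinates with a fitted functional mode
#'
#' @param object fma_model
#' @param newdata matrix/feature_table of frames
#' @param ... unused
#' @return numeric predictions of the query
#' @export
predict.fma_model <- function(object, newdata, ...) {
  X <- pool_rows(newdata)
  as.numeric(sweep(X, 2L, object$mean) %*% object$coef) + object$query_mean
}

#' RMSF of the mode-filtered trajectory
#'
#' Projects each frame onto the functional mode and rebuilds the trajectory
#' from that single collective coordinate (`mean + projection * mode`), then
#' computes the per-residue root mean square fluctuation of the filtered
#' trajectory. Residues the mode does not touch have zero filtered RMSF;
#' every filtered RMSF is bounded by the unfiltered one.
#'
#' @param model fma_model
#' @param data frames the model layout applies to
#' @param residue_map integer vector, one residue id per column of `data`
#'   (e.g. each residue contributing its x, y, z columns); default: one
#'   residue per column
#' @return object of class `rmsf_profile`: data.frame with residue and
#'   rmsf_nm (filtered), plus unfiltered values
#' @export
filtered_rmsf <- function(model, data, residue_map = NULL) {
  X <- pool_rows(data)
  if (ncol(X) != length(model$mode))
    stopf("coordinate layout mismatch: %d columns vs mode length %d",
          ncol(X), length(model$mode))
  if (is.null(residue_map)) residue_map <- seq_len(ncol(X))
  Xc <- sweep(X, 2L, model$mean)
  proj <- Xc %*% model$mode          # scalar collective coordinate
  filt <- proj %*% t(model$mode)     # deviations of the filtered trajectory
  rmsf_of <- function(dev) {
    persq <- colMeans(sweep(dev, 2L, colMeans(dev))^2)
    sq <- tapply(persq, residue_map, sum)
    sqrt(sq)
  }
  res <- sort(unique(residue_map))
  structure(list(profile = data.frame(residue = res,
                                      rmsf_nm = as.numeric(rmsf_of(filt)),
                                      rmsf_unfiltered_nm = as.numeric(rmsf_of(Xc))),
                 mode_norm = sqrt(sum(model$mode^2))),
            class = "rmsf_profile")
}
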