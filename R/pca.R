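#' Principal component analysis over pooled ensembles
#'
#' PCA of pooled, superposed conformations (or any generic design matrix):
#' eigendecomposition of the covariance about the pooled mean. The first
#' component of an occluding ensemble captures the bundle-domain tilt toward
#' the scaffold; projecting every ligand condition onto one common model
#' makes their motions directly comparable. Eigenvector signs follow the
#' largest-entry-positive convention so results are deterministic.
#'
#' @param data matrix (frames x coordinates), or a list of such matrices
#'   pooled row-wise; all inputs must share the coordinate layout (already
#'   superposed to a common reference when they are Cartesian coordinates)
#' @return object of class `pca_model`: `mean`, `vectors` (orthonormal
#'   columns), `values` (descending), `hash`
#' @export
fit_pca <- function(data) {
  X <- pool_rows(data)
  if (nrow(X) < 2L) stopf("need >= 2 frames for PCA")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  cv <- crossprod(Xc) / (nrow(X) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  V <- apply(eg$vectors, 2L, fix_sign)
  values <- pmax(eg$values, 0)
  model <- structure(list(mean = mu, vectors = V, values = values),
                     class = "pca_model")
  model$hash <- object_hash(list(mu, V, values))
  model
}

pool_rows <- function(data) {
  if (is.list(data) && !is.data.frame(data))
    data <- do.call(rbind, lapply(data, as_design_matrix))
  as_design_matrix(data)
}

as_design_matrix <- function(x) {
  if (inherits(x, "feature_table")) x <- as.data.frame(x)[-1]
  as.matrix(x)
}

# deterministic sign: the largest-magnitude entry is positive (ties: lowest
# index wins)
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Project data onto principal components
#'
#' Centered dot products with the model's eigenvectors. Projecting the
#' training data reproduces per-component variances equal to the
#' eigenvalues.
#'
#' @param model pca_model
#' @param data matrix / feature_table / list thereof, same coordinate layout
#' @param components which components (default 1:2)
#' @return matrix of scores (frames x components)
#' @export
pca_project <- function(model, data, components = 1:2) {
  X <- pool_rows(data)
  if (ncol(X) != length(model$mean))
    stopf("dimension mismatch: data has %d columns, model %d", ncol(X),
          length(model$mean))
  S <- sweep(X, 2L, model$mean) %*% model$vectors[, components, drop = FALSE]
  colnames(S) <- paste0("PC", components)
  S
}
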