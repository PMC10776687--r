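#' Free-energy surface from a Markov state model
#'
#' Bins the stationary distribution of an MSM over a regular IC1 x IC2 grid
#' and converts bin weights to Gibbs free energies,
#' \deqn{G(S_i) = -k_B T \ln \sum_{j \in S_i} \pi_j,}
#' where the sum runs over the microstates whose cluster centres fall in
#' bin i. Energies are shifted so the minimum over occupied bins is zero;
#' empty bins are masked. At the default 310 K, kT = 2.5775 kJ/mol.
#'
#' Two equivalent reweighting schemes are provided. The default
#' (`method = "frames"`) spreads each microstate's stationary weight evenly
#' over its member frames and bins those, so the surface keeps bin-level
#' resolution (this is the field-standard trajectory-reweighting estimate).
#' `method = "centers"` assigns each microstate's whole weight to the bin
#' holding its cluster centre; it is only faithful when microstates are much
#' denser than bins.
#'
#' @param model msm_model
#' @param disc discretization whose centres the model's states refer to
#' @param grid optional `list(x = edges, y = edges)`; default a regular
#'   `n_bins` x `n_bins` grid over the centre range padded by 5 percent
#' @param n_bins bins per axis for the default grid (default 50)
#' @param temperature_K temperature, K (default 310)
#' @param method "frames" (reweighted frame histogram, default) or
#'   "centers" (whole microstate weight at the centre bin)
#' @param projections list of n x 2 matrices (the IC coordinates the
#'   discretization was built from), needed for `method = "frames"` when the
#'   discretization does not carry them; defaults to `disc$projections`
#' @param dtrajs discrete trajectories matching `projections`; defaults to
#'   `disc$dtrajs`
#' @return `free_energy_surface` with per-bin `G` (kJ/mol), `weight`
#'   (summed stationary mass) and `occupied` mask
#' @export
free_energy_surface <- function(model, disc, grid = NULL, n_bins = 50L,
                                temperature_K = 310,
                                method = c("frames", "centers"),
                                projections = NULL, dtrajs = NULL) {
  method <- match.arg(method)
  if (ncol(disc$centers) < 2L) stopf("need >= 2 independent components to bin")
  if (is.null(grid)) grid <- default_grid(disc$centers[, 1:2, drop = FALSE], n_bins)
  nx <- length(grid$x) - 1L
  ny <- length(grid$y) - 1L
  W <- matrix(0, nx, ny)
  if (method == "centers") {
    centers <- disc$centers[model$active + 1L, , drop = FALSE]
    ix <- bin_index(centers[, 1], grid$x)
    iy <- bin_index(centers[, 2], grid$y)
    if (any(is.na(ix)) || any(is.na(iy)))
      stopf("%d microstate centre(s) fall outside the grid",
            sum(is.na(ix) | is.na(iy)))
    for (i in seq_along(ix))
      W[ix[i], iy[i]] <- W[ix[i], iy[i]] + model$pi[i]
  } else {
    projections <- projections %||% disc$projections
    dtrajs <- dtrajs %||% disc$dtrajs
    if (is.null(projections))
      stopf("method = 'frames' needs the IC projections (pass `projections` or use a discretization that carries them)")
    if (!is.list(projections)) projections <- list(projections)
    if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
    xy <- do.call(rbind, lapply(projections, function(m) as.matrix(m)[, 1:2, drop = FALSE]))
    st <- unlist(dtrajs)
    if (nrow(xy) != length(st))
      stopf("projections (%d frames) and dtrajs (%d) do not match", nrow(xy), length(st))
    # stationary weight per frame: pi_i spread over the N_i member frames
    in_active <- st %in% model$active
    st_idx <- match(st, model$active)
    n_per_state <- tabulate(st_idx[in_active], nbins = length(model$active))
    wfr <- ifelse(in_active, model$pi[st_idx] / n_per_state[st_idx], 0)
    ix <- bin_index(xy[, 1], grid$x)
    iy <- bin_index(xy[, 2], grid$y)
    keep <- !is.na(ix) & !is.na(iy) & wfr > 0
    if (!any(keep)) stopf("no frames fall inside the grid")
    flat <- (iy[keep] - 1L) * nx + ix[keep]
    acc <- rowsum(wfr[keep], flat)
    W[as.integer(rownames(acc))] <- acc
    W <- W / sum(W)
  }
  kT <- kT_kjmol(temperature_K)
  occupied <- W > 0
  G <- matrix(NA_real_, nx, ny)
  G[occupied] <- -kT * log(W[occupied])
  G[occupied] <- G[occupied] - min(G[occupied])
  out <- new_surface(G, grid, kT = kT, occupied = occupied)
  out$weight <- W
  out
}

default_grid <- function(xy, n_bins) {
  pad <- function(r) r + c(-1, 1) * 0.05 * diff(r)
  rx <- pad(range(xy[, 1]))
  ry <- pad(range(xy[, 2]))
  list(x = seq(rx[1], rx[2], length.out = n_bins + 1L),
       y = seq(ry[1], ry[2], length.out = n_bins + 1L))
}

bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Compare two free-energy surfaces on their shared occupied support
#'
#' Both surfaces are re-shifted so their minimum over the shared support is
#' zero (the Eq.-style min = 0 convention applied to the common bins), then
#' compared per bin. Estimated surfaces carry a `weight` matrix; bins below
#' `weight_min` are excluded as statistically unoccupied.
#'
#' @param est estimated free_energy_surface (with weights)
#' @param ref reference surface on the same grid (e.g. [analytic_surface()])
#' @param weight_min minimum stationary mass for a bin to count (default 1e-3)
#' @return list: `max_abs_kjmol`, `rmse_kjmol`, `n_bins`, `max_abs_kT`
#' @export
compare_surfaces <- function(est, ref, weight_min = 1e-3) {
  if (!all(dim(est$G) == dim(ref$G)))
    stopf("surfaces must share one grid (%dx%d vs %dx%d)",
          nrow(est$G), ncol(est$G), nrow(ref$G), ncol(ref$G))
  shared <- est$occupied & ref$occupied
  if (!is.null(est$weight)) shared <- shared & est$weight > weight_min
  if (!any(shared)) stopf("no shared occupied bins")
  a <- est$G[shared] - min(est$G[shared])
  b <- ref$G[shared] - min(ref$G[shared])
  d <- a - b
  list(max_abs_kjmol = max(abs(d)), rmse_kjmol = sqrt(mean(d^2)),
       n_bins = sum(shared), max_abs_kT = max(abs(d)) / est$kT)
}

#' Bootstrap robustness of the free-energy surface
#'
#' Resamples whole trajectories with replacement and re-runs the
#' MSM-estimation half of the chain (counts, reversible estimate, surface)
#' with the tICA projection and cluster centres held fixed from the full
#' dataset, so all replicate surfaces live on one support and per-bin mean
#' and SD are well defined. Replicates without a connected set are redrawn
#' (at most 10 attempts each). Bins unoccupied in a replicate do not
#' contribute to that replicate's statistics.
#'
#' @param disc discretization of the full dataset (holds the dtrajs)
#' @param lag_ns,dt_ns MSM lag and frame spacing, ns
#' @param grid optional shared grid; default from the discretization centres
#' @param n_bins bins per axis for the default grid
#' @param n_boot number of bootstrap replicates (default 100)
#' @param seed integer seed
#' @param temperature_K temperature, K
#' @return list: `mean` and `sd` (free_energy_surface objects), `n_boot`,
#'   `n_contrib` (replicates contributing per bin)
#' @export
bootstrap_surface <- function(disc, lag_ns = 25, dt_ns = 0.5, grid = NULL,
                              n_bins = 50L, n_boot = 100L, seed = NULL,
                              temperature_K = 310) {
  if (n_boot < 2L) stopf("n_boot must be >= 2")
  if (length(disc$dtrajs) < 2L) stopf("need >= 2 trajectories to bootstrap")
  if (is.null(grid)) grid <- default_grid(disc$centers[, 1:2, drop = FALSE], n_bins)
  nx <- length(grid$x) - 1L
  ny <- length(grid$y) - 1L
  sum1 <- sum2 <- nocc <- matrix(0, nx, ny)
  kT <- kT_kjmol(temperature_K)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(10L)) {
        idx <- sample.int(length(disc$dtrajs), replace = TRUE)
        m <- try(suppressWarnings(
          estimate_msm(disc$dtrajs[idx], lag_ns = lag_ns, dt_ns = dt_ns)),
          silent = TRUE)
        if (!inherits(m, "try-error")) break
        if (attempt == 10L) stopf("bootstrap replicate failed 10 times (disconnected data)")
      }
      s <- free_energy_surface(m, disc, grid = grid,
                               temperature_K = temperature_K,
                               projections = if (!is.null(disc$projections))
                                 disc$projections[idx] else NULL,
                               dtrajs = disc$dtrajs[idx])
      occ <- s$occupied
      sum1[occ] <- sum1[occ] + s$G[occ]
      sum2[occ] <- sum2[occ] + s$G[occ]^2
      nocc[occ] <- nocc[occ] + 1
    }
  })
  occ <- nocc > 0
  Gm <- matrix(NA_real_, nx, ny)
  Gs <- matrix(NA_real_, nx, ny)
  Gm[occ] <- sum1[occ] / nocc[occ]
  v <- pmax(sum2[occ] / nocc[occ] - (sum1[occ] / nocc[occ])^2, 0)
  Gs[occ] <- sqrt(v)
  mean_s <- new_surface(Gm, grid, kT = kT, occupied = occ)
  sd_s <- new_surface(Gs, grid, kT = kT, occupied = occ)
  list(mean = mean_s, sd = sd_s, n_boot = n_boot, n_contrib = nocc)
}

#' Write a surface, ITS curve or CK table as annotated delimited text
#'
#' Metadata lines are prefixed with `#` followed by a tab-separated body.
#'
#' @param x free_energy_surface, its_curve or ck_result
#' @param path output file
#' @param meta named list of extra metadata to record
#' @return `path`, invisibly
#' @export
write_analysis_table <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  put_meta <- function(...) writeLines(sprintf("# %s", sprintf(...)), con)
  if (inherits(x, "free_energy_surface")) {
    put_meta("type: free_energy_surface")
    put_meta("kT_kjmol: %.6g", x$kT)
    for (nm in names(meta)) put_meta("%s: %s", nm, format(meta[[nm]]))
    df <- expand.grid(ix = seq_along(x$x_centers), iy = seq_along(x$y_centers))
    df$IC1 <- x$x_centers[df$ix]
    df$IC2 <- x$y_centers[df$iy]
    df$G_kjmol <- as.numeric(x$G)[df$ix + (df$iy - 1L) * nrow(x$G)]
    df$occupied <- as.logical(x$occupied)[df$ix + (df$iy - 1L) * nrow(x$G)]
    utils::write.table(df[, c("IC1", "IC2", "G_kjmol", "occupied")], con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    put_meta("type: %s", class(x)[1])
    for (nm in names(meta)) put_meta("%s: %s", nm, format(meta[[nm]]))
    utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
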