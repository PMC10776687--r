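#' Sample a discrete Markov chain
#'
#' Oracle generator for the Markov-state-model estimators: simulates a chain
#' with a known row-stochastic transition matrix so that estimation can be
#' checked against the generating truth.
#'
#' @param P row-stochastic K x K transition matrix (rows sum to 1 within 1e-10)
#' @param n_steps chain length (including the initial state)
#' @param seed integer seed (reproducible)
#' @param init optional initial state, 0-based; default drawn uniformly
#' @return integer vector of 0-based state indices, length `n_steps`
#' @export
simulate_discrete_chain <- function(P, n_steps, seed = NULL, init = NULL) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stopf("transition matrix must be square")
  if (any(P < 0)) stopf("transition matrix entries must be >= 0")
  if (any(abs(rowSums(P) - 1) > 1e-10))
    stopf("rows of the transition matrix must sum to 1 (tolerance 1e-10)")
  if (n_steps < 1L) stopf("n_steps must be >= 1")
  cumP <- t(apply(P, 1L, cumsum))
  with_seed(seed, {
    if (is.null(init)) init <- sample.int(nrow(P), 1L) - 1L
    u <- runif(n_steps - 1L)
    markov_sample_cpp(cumP, as.integer(init), u)
  })
}

#' Overdamped Langevin dynamics on a latent occlusion potential
#'
#' Euler-Maruyama integration of
#' \deqn{x \leftarrow x - (D/kT)\,\nabla U\,dt + \sqrt{2 D\,dt}\,\xi,}
#' the synthetic stand-in for unbiased MD sampling of the occlusion
#' coordinate. Long runs equilibrate to the Boltzmann distribution
#' exp(-U/kT), which is what the free-energy estimators are validated
#' against.
#'
#' @param pot potential_spec
#' @param n_steps number of frames (the first frame is the initial position)
#' @param dt time step, ns (default 0.5 so lag times in ns map to integer
#'   frame lags)
#' @param diffusion diffusion constant, latent unit^2 per ns
#' @param seed integer seed
#' @param x0 initial position; default the centre of the deepest well
#' @param profile optional ligand_profile carried along for emission
#' @return object of class `latent_trajectory`
#' @export
simulate_langevin <- function(pot, n_steps, dt = 0.5, diffusion = 0.01,
                              seed = NULL, x0 = NULL, profile = NULL) {
  stopifnot(inherits(pot, "potential_spec"))
  if (n_steps < 2L) stopf("n_steps must be >= 2")
  assert_scalar_num(dt, "dt", positive = TRUE)
  assert_scalar_num(diffusion, "diffusion", positive = TRUE)
  p <- potential_parts(pot)
  if (is.null(x0)) x0 <- p$centers[which.max(p$depths), ]

  # stability heuristic: the drift per step must stay below the narrowest
  # well width, otherwise basins can be overstepped
  gmax <- max_gradient_estimate(pot)
  if (dt * diffusion * gmax / pot$kT >= min(p$widths))
    warnf("time step too coarse: drift per step (%.3g) exceeds the narrowest well width (%.3g); reduce dt or diffusion",
          dt * diffusion * gmax / pot$kT, min(p$widths))

  coords <- with_seed(seed, {
    noise <- matrix(rnorm(2L * (n_steps - 1L)), ncol = 2L)
    langevin_cpp(p$centers, p$depths, p$widths, pot$confinement, pot$kT,
                 as.numeric(x0), as.integer(n_steps), dt, diffusion, noise)
  })
  structure(list(coords = coords, dt = dt, seed = seed, profile = profile,
                 potential = pot),
            class = "latent_trajectory")
}

max_gradient_estimate <- function(pot, n = 41L) {
  p <- potential_parts(pot)
  lo <- apply(p$centers - 3 * p$widths, 2, min)
  hi <- apply(p$centers + 3 * p$widths, 2, max)
  gx <- seq(lo[1], hi[1], length.out = n)
  gy <- seq(lo[2], hi[2], length.out = n)
  pts <- cbind(rep(gx, times = n), rep(gy, each = n))
  g <- matrix(0, nrow(pts), 2L)
  g[, 1] <- 2 * pot$confinement * pts[, 1]
  g[, 2] <- 2 * pot$confinement * pts[, 2]
  for (w in seq_along(p$depths)) {
    dx <- pts[, 1] - p$centers[w, 1]
    dy <- pts[, 2] - p$centers[w, 2]
    e <- p$depths[w] * exp(-0.5 * ((dx / p$widths[w, 1])^2 + (dy / p$widths[w, 2])^2))
    g[, 1] <- g[, 1] + e * dx / p$widths[w, 1]^2
    g[, 2] <- g[, 2] + e * dy / p$widths[w, 2]^2
  }
  max(sqrt(rowSums(g^2)))
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf("<latent_trajectory> %d frames, dt = %g ns%s\n",
              nrow(x$coords), x$dt,
              if (!is.null(x$profile)) paste0(", profile ", x$profile$name) else ""))
  invisible(x)
}

#' Emit observables from a latent occlusion trajectory
#'
#' Maps the latent occlusion coordinate to the package's observable set:
#' outer-gate and inner-gate distances interpolate affinely between their
#' outward-open and occluded endpoints, and ligand-residue interaction
#' energies interpolate between their weak (outward-open) and strong
#' (occluded) values; all observables receive i.i.d. Gaussian noise. The
#' occlusion progress is 0 at the outward-open well centre and 1 at the
#' occluded well centre.
#'
#' @param traj latent_trajectory carrying a ligand_profile
#' @param noise_sigma Gaussian emission noise for distance observables, nm.
#'   Either a scalar or a named vector per observable.
#' @param seed integer seed for the emission noise
#' @param observables optional subset of observable names; default all
#'   configured in the profile
#' @return feature_table with `time_ns`, the distance columns and the energy
#'   columns
#' @export
emit_features <- function(traj, noise_sigma = 0.02, seed = NULL,
                          observables = NULL) {
  profile <- traj$profile
  if (is.null(profile)) stopf("trajectory carries no ligand profile")
  means <- profile$emission_means
  energies <- profile$energy
  all_obs <- c(names(means), names(energies))
  if (is.null(observables)) observables <- all_obs
  missing <- setdiff(observables, all_obs)
  if (length(missing))
    stopf("no emission mean configured for: %s", paste(missing, collapse = ", "))

  # occlusion progress: 0 at the OO well centre, 1 at the OC well centre
  s <- (traj$coords[, 1] - profile$oo_center[1]) /
    (profile$oc_center[1] - profile$oo_center[1])
  n <- length(s)
  sigma_for <- function(obs) {
    if (!is.null(names(noise_sigma)) && obs %in% names(noise_sigma))
      noise_sigma[[obs]]
    else if (is.null(names(noise_sigma))) noise_sigma[1] else 0
  }
  cols <- with_seed(seed, {
    out <- list()
    for (obs in observables) {
      if (obs %in% names(means)) {
        ep <- means[[obs]]
        out[[obs]] <- ep[["oo"]] + s * (ep[["oc"]] - ep[["oo"]]) +
          rnorm(n, sd = sigma_for(obs))
      } else {
        ep <- energies[[obs]]
        out[[obs]] <- ep[["oo"]] + s * (ep[["oc"]] - ep[["oo"]]) +
          rnorm(n, sd = profile$energy_noise)
      }
    }
    out
  })
  feature_table(seq(0, by = traj$dt, length.out = n), cols)
}

#' Replica ensemble for one ligand condition
#'
#' Emulates a set of independent production runs for a ligand condition:
#' each replica is an independent Langevin trajectory on the profile's
#' two-basin potential, emitted as a feature table. Replica simulation seeds
#' are `seed + replica_index`; emission seeds are offset by 500000 so
#' trajectory and emission noise streams never coincide.
#'
#' @param profile ligand_profile
#' @param n_replicas number of replicas (default 10)
#' @param n_steps frames per replica
#' @param seed master seed
#' @param dt,diffusion integrator settings, see [simulate_langevin()]
#' @param noise_sigma emission noise, see [emit_features()]
#' @return list of feature_table, one per replica, with attribute "latent"
#'   holding the latent trajectories
#' @export
make_ligand_ensemble <- function(profile, n_replicas = 10L, n_steps = 20000L,
                                 seed = 1L, dt = 0.5, diffusion = 0.01,
                                 noise_sigma = 0.02) {
  if (n_replicas < 1L) stopf("n_replicas must be >= 1")
  pot <- profile_potential(profile)
  latents <- vector("list", n_replicas)
  tables <- vector("list", n_replicas)
  for (i in seq_len(n_replicas)) {
    latents[[i]] <- simulate_langevin(pot, n_steps, dt = dt,
                                      diffusion = diffusion,
                                      seed = seed + i, profile = profile)
    tables[[i]] <- emit_features(latents[[i]], noise_sigma = noise_sigma,
                                 seed = seed + 500000L + i)
  }
  names(tables) <- paste0(profile$name, "_rep", seq_len(n_replicas))
  attr(tables, "latent") <- latents
  tables
}
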