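#' Gaussian-well potential on the latent occlusion plane
#'
#' The synthetic stand-in for the conformational free-energy landscape of
#' transporter occlusion: a 2-D potential built from inverted Gaussian wells
#' plus a weak harmonic confinement,
#' \deqn{U(x) = -\sum_w d_w \exp(-\|x - c_w\|^2 / 2\sigma_w^2) + \kappa \|x\|^2.}
#' The first latent axis is the occlusion coordinate (outward-open basin at
#' positive values, occluded basin at negative values); the second axis is a
#' fast orthogonal mode.
#'
#' @param wells list of wells, each `list(center = c(x, y), depth = kJ/mol,
#'   width = c(sx, sy))` (width is the per-axis Gaussian sigma, dimensionless)
#' @param confinement harmonic constant, kJ/mol per unit^2
#' @param kT thermal energy, kJ/mol (default 310 K)
#' @return object of class `potential_spec`
#' @export
potential_spec <- function(wells, confinement = 1.0, kT = kT_kjmol(310)) {
  if (length(wells) < 1L) stopf("need at least one well")
  for (w in wells) {
    if (length(w$center) != 2L || !all(is.finite(w$center)))
      stopf("each well needs a finite 2-vector center")
    assert_scalar_num(w$depth, "depth", positive = TRUE)
    wd <- rep_len(w$width, 2L)
    if (any(wd <= 0)) stopf("well widths must be > 0")
  }
  assert_scalar_num(confinement, "confinement")
  if (confinement < 0) stopf("confinement must be >= 0")
  assert_scalar_num(kT, "kT", positive = TRUE)
  structure(list(wells = wells, confinement = confinement, kT = kT),
            class = "potential_spec")
}

# matrix/vector views used by the integrator and the surface oracle
potential_parts <- function(pot) {
  list(
    centers = do.call(rbind, lapply(pot$wells, function(w) w$center)),
    depths = vapply(pot$wells, function(w) w$depth, 1.0),
    widths = do.call(rbind, lapply(pot$wells, function(w) rep_len(w$width, 2L)))
  )
}

#' Evaluate a Gaussian-well potential
#'
#' @param pot potential_spec
#' @param x n x 2 matrix (or 2-vector) of latent positions
#' @return potential energy in kJ/mol per row
#' @export
potential_energy <- function(pot, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  p <- potential_parts(pot)
  u <- pot$confinement * rowSums(x^2)
  for (w in seq_along(p$depths)) {
    q <- ((x[, 1] - p$centers[w, 1]) / p$widths[w, 1])^2 +
      ((x[, 2] - p$centers[w, 2]) / p$widths[w, 2])^2
    u <- u - p$depths[w] * exp(-0.5 * q)
  }
  u
}

#' Boltzmann-inversion oracle surface
#'
#' Evaluates the potential at bin centres of a regular grid and shifts it so
#' the minimum over the grid is zero. In the low-noise narrow-bin limit this
#' is the exact free-energy surface a perfectly converged Markov-state-model
#' estimate must recover, so it serves as the independent ground truth for
#' the estimation chain.
#'
#' @param pot potential_spec
#' @param grid optional `list(x = edges, y = edges)` of bin edges; default: a
#'   regular `n_bins` x `n_bins` grid covering all well centres +/- 3 sigma
#'   (error if a user grid fails to cover that region)
#' @param n_bins bins per axis for the default grid
#' @return object of class `free_energy_surface`
#' @export
analytic_surface <- function(pot, grid = NULL, n_bins = 50L) {
  p <- potential_parts(pot)
  lo <- apply(p$centers - 3 * p$widths, 2, min)
  hi <- apply(p$centers + 3 * p$widths, 2, max)
  if (is.null(grid)) {
    grid <- list(x = seq(lo[1], hi[1], length.out = n_bins + 1L),
                 y = seq(lo[2], hi[2], length.out = n_bins + 1L))
  } else {
    if (min(grid$x) > lo[1] || max(grid$x) < hi[1] ||
        min(grid$y) > lo[2] || max(grid$y) < hi[2])
      stopf("grid must cover all well centres +/- 3 sigma")
  }
  xc <- midpoints(grid$x)
  yc <- midpoints(grid$y)
  pts <- cbind(rep(xc, times = length(yc)), rep(yc, each = length(xc)))
  G <- matrix(potential_energy(pot, pts), nrow = length(xc))
  G <- G - min(G)
  new_surface(G, grid, kT = pot$kT, occupied = matrix(TRUE, nrow(G), ncol(G)))
}

midpoints <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

new_surface <- function(G, grid, kT, occupied) {
  structure(list(G = G, x_edges = grid$x, y_edges = grid$y,
                 x_centers = midpoints(grid$x), y_centers = midpoints(grid$y),
                 kT = kT, occupied = occupied),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("<free_energy_surface> %d x %d bins, %d occupied, kT = %.4f kJ/mol, max G = %.2f kJ/mol\n",
              nrow(x$G), ncol(x$G), sum(x$occupied), x$kT,
              max(x$G[x$occupied])))
  invisible(x)
}

#' Ligand condition profiles for the synthetic occlusion world
#'
#' A ligand profile states how a bound compound shapes the latent two-basin
#' landscape (relative depths of the outward-open and occluded wells) and how
#' latent positions are emitted as observables: gate distances interpolate
#' between configured outward-open (OO) and occluded (OC) endpoints, and the
#' ligand-F335 / ligand-D98 interaction energies are affine in the occlusion
#' coordinate with Gaussian noise.
#'
#' The six stock profiles returned by [default_ligand_profiles()] encode the
#' qualitative depth ordering of the ligand series: the occluded basin
#' dominates for serotonin, the two basins are of comparable depth for the
#' propyl analogue, the outward-open basin dominates for the butyl analogue,
#' and the methyl analogue and cocaine barely populate the occluded basin.
#'
#' @param name condition label, e.g. "5HT", "M5HT", "P5HT", "B5HT", "COC", "apo"
#' @param oo_depth,oc_depth well depths in kJ/mol
#' @param energy named list of interaction-energy endpoints, each `c(oo=, oc=)`
#'   in kJ/mol
#' @param energy_noise emission noise sigma for energy observables, kJ/mol
#' @param emission_means named list of observable endpoints, each `c(oo=, oc=)`
#'   in nm
#' @param oo_center,oc_center 2-vector well centres in latent space
#' @param curvature harmonic curvature of each well bottom, kJ/mol per
#'   unit^2; well widths are `sqrt(depth / curvature)` so that all basins
#'   share one local curvature and the basin weights follow the Boltzmann
#'   factor of the depth difference alone
#' @param confinement,kT passed to the potential
#' @return object of class `ligand_profile`
#' @export
ligand_profile <- function(name, oo_depth, oc_depth,
                           energy = substrate_energy_endpoints(),
                           energy_noise = 2,
                           emission_means = default_emission_endpoints(),
                           oo_center = c(1.5, 0), oc_center = c(-1.5, 0),
                           curvature = 40, confinement = 2.0,
                           kT = kT_kjmol(310)) {
  assert_scalar_num(oo_depth, "oo_depth", positive = TRUE)
  assert_scalar_num(oc_depth, "oc_depth", positive = TRUE)
  known_order <- list("5HT" = "oc", "B5HT" = "oo", "COC" = "oo", "M5HT" = "oo")
  if (name %in% names(known_order)) {
    dominant <- known_order[[name]]
    ok <- if (dominant == "oc") oc_depth > oo_depth else oo_depth > oc_depth
    if (!ok) stopf("profile '%s' must have the %s basin deeper", name, dominant)
  }
  structure(list(name = name, oo_depth = oo_depth, oc_depth = oc_depth,
                 energy = energy, energy_noise = energy_noise,
                 emission_means = emission_means,
                 oo_center = oo_center, oc_center = oc_center,
                 curvature = curvature, confinement = confinement, kT = kT),
            class = "ligand_profile")
}

#' @rdname ligand_profile
#' @export
default_emission_endpoints <- function() {
  # OO > OC for the outer-gate distances; inner-gate distances widen with
  # occlusion. Stand-in endpoints (reference structures not bundled),
  # config-overridable.
  list(
    tm6a_tm9up_nm = c(oo = 1.75, oc = 1.35),
    tm1b_tm9up_nm = c(oo = 1.45, oc = 1.10),
    d87_f268_nm   = c(oo = 0.80, oc = 1.00),
    d87_v281_nm   = c(oo = 0.90, oc = 1.15),
    f268_y289_nm  = c(oo = 0.55, oc = 0.75)
  )
}

#' @rdname ligand_profile
#' @export
substrate_energy_endpoints <- function() {
  # places the -20 kJ/mol split between the basins: weak interaction in the
  # outward-open well, strong in the occluded well
  list(e_f335_kjmol = c(oo = -5, oc = -35),
       e_d98_kjmol = c(oo = -10, oc = -30))
}

#' @rdname ligand_profile
#' @export
default_ligand_profiles <- function() {
  inhib_energy <- list(e_f335_kjmol = c(oo = -5, oc = -17),
                       e_d98_kjmol = c(oo = -12, oc = -17))
  apo_energy <- list(e_f335_kjmol = c(oo = 0, oc = 0),
                     e_d98_kjmol = c(oo = 0, oc = 0))
  list(
    `5HT`  = ligand_profile("5HT",  oo_depth = 10.0, oc_depth = 16.0),
    P5HT   = ligand_profile("P5HT", oo_depth = 13.0, oc_depth = 13.0),
    B5HT   = ligand_profile("B5HT", oo_depth = 14.5, oc_depth = 11.5),
    M5HT   = ligand_profile("M5HT", oo_depth = 16.0, oc_depth = 9.0),
    COC    = ligand_profile("COC",  oo_depth = 16.0, oc_depth = 8.5,
                            energy = inhib_energy),
    apo    = ligand_profile("apo",  oo_depth = 15.0, oc_depth = 9.5,
                            energy = apo_energy)
  )
}

#' Shared bin grid covering a potential and sampled points
#'
#' Builds one regular grid that simultaneously covers all well centres
#' +/- 3 sigma of a potential and every supplied point (padded 2 percent),
#' so an estimated surface and the [analytic_surface()] oracle can be
#' compared bin by bin.
#'
#' @param pot potential_spec
#' @param points n x 2 matrix of sampled positions (e.g. microstate centres)
#' @param n_bins bins per axis
#' @return `list(x = edges, y = edges)`
#' @export
shared_grid <- function(pot, points, n_bins = 50L) {
  p <- potential_parts(pot)
  lo_w <- apply(p$centers - 3 * p$widths, 2, min)
  hi_w <- apply(p$centers + 3 * p$widths, 2, max)
  rng <- function(axis) {
    r <- range(points[, axis])
    pad <- 0.02 * diff(r)
    c(min(r[1] - pad, lo_w[axis]), max(r[2] + pad, hi_w[axis]))
  }
  rx <- rng(1)
  ry <- rng(2)
  list(x = seq(rx[1], rx[2], length.out = n_bins + 1L),
       y = seq(ry[1], ry[2], length.out = n_bins + 1L))
}

#' Two-basin potential with a stated free-energy difference
#'
#' Benchmark construction for the free-energy recovery tests: two wells of
#' identical depth and width whose stationary free-energy difference comes
#' from the harmonic confinement alone (the occluded well sits at a larger
#' radius). Because the wells are congruent, all curvature and
#' anharmonicity corrections cancel and the basin occupancy ratio equals
#' `exp(delta_kT)` up to the small confinement-tilt correction, making the
#' Boltzmann-inversion oracle the exact reference.
#'
#' @param delta_kT free-energy difference between the basins in units of kT
#'   (positive = the occluded basin at negative latent x is favoured)
#' @param depth common well depth, kJ/mol (deep enough that the confinement
#'   plateau between the basins carries negligible weight)
#' @param curvature well-bottom curvature, kJ/mol per unit^2
#' @param confinement harmonic confinement, kJ/mol per unit^2
#' @param r_oc radius of the occluded well centre
#' @param kT thermal energy, kJ/mol
#' @return potential_spec
#' @export
two_basin_potential <- function(delta_kT = 2, depth = 12, curvature = 60,
                                confinement = 2, r_oc = 1.2,
                                kT = kT_kjmol(310)) {
  r_oo <- sqrt(r_oc^2 + delta_kT * kT / confinement)
  w <- rep(sqrt(depth / curvature), 2L)
  potential_spec(list(
    list(center = c(r_oo, 0), depth = depth, width = w),
    list(center = c(-r_oc, 0), depth = depth, width = w)),
    confinement = confinement, kT = kT)
}

#' Potential induced by a ligand profile
#'
#' @param profile ligand_profile
#' @return potential_spec with the profile's two wells
#' @export
profile_potential <- function(profile) {
  w <- function(depth) rep_len(sqrt(depth / profile$curvature), 2L)
  potential_spec(
    wells = list(
      list(center = profile$oo_center, depth = profile$oo_depth,
           width = w(profile$oo_depth)),
      list(center = profile$oc_center, depth = profile$oc_depth,
           width = w(profile$oc_depth))
    ),
    confinement = profile$confinement, kT = profile$kT
  )
}
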