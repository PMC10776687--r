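test_that("discrete chains reproduce their generating matrix", {
  # absorbing identity
  expect_equal(unique(simulate_discrete_chain(diag(2), 50, seed = 1, init = 1L)), 1L)

  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  x <- simulate_discrete_chain(P, 200000, seed = 42)
  emp <- prop.table(table(factor(x[-length(x)], 0:1),
                          factor(x[-1], 0:1)), margin = 1)
  expect_lt(max(abs(emp - P)), 0.005)
  # pi = (2/3, 1/3) solved by hand from pi P = pi
  expect_lt(abs(mean(x == 0) - 2 / 3), 0.01)

  expect_error(simulate_discrete_chain(matrix(c(0.9, 0.2, 0.2, 0.8), 2), 10),
               "sum to 1")
  expect_error(simulate_discrete_chain(matrix(c(1.5, -0.5, 0, 1), 2, byrow = TRUE), 10),
               ">= 0")
  # determinism
  expect_identical(simulate_discrete_chain(P, 1000, seed = 7),
                   simulate_discrete_chain(P, 1000, seed = 7))
})

test_that("Langevin sampling equilibrates to the Boltzmann distribution", {
  # near-pure harmonic confinement: per-axis variance kT/(2c)
  pot <- potential_spec(list(list(center = c(0, 0), depth = 1e-9, width = 5)),
                        confinement = 2, kT = kT310)
  tr <- simulate_langevin(pot, 5e5, dt = 0.1, diffusion = 0.02, seed = 4)
  expect_lt(abs(var(tr$coords[, 1]) / (kT310 / (2 * 2)) - 1), 0.08)
  expect_lt(abs(var(tr$coords[, 2]) / (kT310 / (2 * 2)) - 1), 0.08)

  # two equal wells: symmetric occupancy
  sym <- two_basin_potential(delta_kT = 0)
  trs <- simulate_langevin(sym, 5e5, dt = 0.1, diffusion = 0.015, seed = 8)
  occ <- mean(trs$coords[, 1] < 0)
  expect_lt(abs(occ - 0.5), 0.06)

  # dU = 2 kT between minima: occupancy ratio matches the Boltzmann
  # quadrature oracle within 15% at 1e6 steps
  pot2 <- two_basin_potential(delta_kT = 2)
  oracle <- boltzmann_ratio(pot2)
  tr2 <- simulate_langevin(pot2, 1e6, dt = 0.1, diffusion = 0.015, seed = 5)
  ratio <- mean(tr2$coords[, 1] < 0) / mean(tr2$coords[, 1] >= 0)
  expect_lt(abs(ratio / oracle - 1), 0.15)

  # determinism: identical seed reproduces the trajectory byte for byte
  tr3 <- simulate_langevin(pot2, 500, dt = 0.1, diffusion = 0.015, seed = 5)
  tr4 <- simulate_langevin(pot2, 500, dt = 0.1, diffusion = 0.015, seed = 5)
  expect_identical(tr3$coords, tr4$coords)
})

test_that("Langevin equilibrium histogram matches exp(-U/kT) within 0.3 kT", {
  pot <- two_basin_potential(delta_kT = 2)
  coords <- do.call(rbind, lapply(1:10, function(r)
    simulate_langevin(pot, 1e5, dt = 0.1, diffusion = 0.015,
                      seed = 200 + r)$coords))
  grid <- shared_grid(pot, coords[seq(1, nrow(coords), by = 50), ], 100)
  ref <- analytic_surface(pot, grid = grid)
  expect_lt(empirical_surface_error(coords, ref), 0.3)
})

test_that("stability precondition warns on overly coarse steps", {
  pot <- two_basin_potential(delta_kT = 2)
  expect_warning(simulate_langevin(pot, 100, dt = 50, diffusion = 1, seed = 1),
                 "time step too coarse")
})

test_that("emission maps the occlusion coordinate onto observables", {
  prof <- default_ligand_profiles()[["5HT"]]
  fake <- structure(list(coords = rbind(prof$oo_center, prof$oc_center),
                         dt = 0.5, seed = 0, profile = prof),
                    class = "latent_trajectory")
  ft <- emit_features(fake, noise_sigma = 0, seed = 1)
  ft$e_f335_kjmol <- ft$e_f335_kjmol  # columns exist
  # frame at the OO well centre reproduces the configured OO endpoint
  expect_equal(ft$tm6a_tm9up_nm[1], 1.75, tolerance = 1e-12)
  expect_equal(ft$tm1b_tm9up_nm[2], 1.10, tolerance = 1e-12)
  # the emitted energy noise is separate from noise_sigma; compare means
  prof0 <- prof
  prof0$energy_noise <- 0
  fake0 <- fake
  fake0$profile <- prof0
  ft0 <- emit_features(fake0, noise_sigma = 0)
  expect_equal(ft0$e_f335_kjmol, c(-5, -35))
  expect_lt(ft0$e_f335_kjmol[2], -20)  # strong-interaction side of the split
  # inner-gate distances widen with occlusion
  expect_gt(ft0$d87_f268_nm[2], ft0$d87_f268_nm[1])
  expect_gt(ft0$d87_v281_nm[2], ft0$d87_v281_nm[1])
  expect_gt(ft0$f268_y289_nm[2], ft0$f268_y289_nm[1])

  # energy and gate distance are affine in the same latent coordinate
  tr <- simulate_langevin(profile_potential(prof), 20000, seed = 2,
                          profile = prof)
  ftn <- emit_features(tr, noise_sigma = 0.02, seed = 3)
  expect_gt(cor(ftn$e_f335_kjmol, ftn$tm6a_tm9up_nm), 0.8)

  expect_error(emit_features(fake, observables = "nonexistent_nm"),
               "nonexistent_nm")
})

test_that("ligand ensembles are reproducible with distinct replicas", {
  prof <- default_ligand_profiles()[["5HT"]]
  e1 <- make_ligand_ensemble(prof, n_replicas = 3, n_steps = 2000, seed = 11)
  e2 <- make_ligand_ensemble(prof, n_replicas = 3, n_steps = 2000, seed = 11)
  attr(e1, "latent") <- attr(e2, "latent") <- NULL
  expect_identical(e1, e2)
  expect_false(identical(e1[[1]], e1[[2]]))

  # a substrate-profile replica set reaches the occluded basin quickly
  ens <- make_ligand_ensemble(prof, n_replicas = 3, n_steps = 1e5, seed = 21)
  lat <- attr(ens, "latent")
  visits <- vapply(lat, function(l)
    any(l$coords[, 1] < prof$oc_center[1] + 0.3), TRUE)
  expect_true(any(visits))
})

test_that("patch-clamp traces follow the stated closed forms", {
  rates <- default_transport_rates()[["5HT"]]
  # zero concentration: flat zero
  z <- simulate_patch_clamp(rates, patch_protocol(concentration_uM = 0))
  expect_true(all(z$current == 0))

  # saturating concentration, zero noise: exactly mono-exponential with the
  # plateau rate (log-linear residual at machine precision)
  tr <- simulate_patch_clamp(rates, patch_protocol(concentration_uM = 1e6))
  expect_equal(tr$k_obs, rates$k_flip, tolerance = 1e-4)
  on <- tr$time_s >= tr$protocol$pulse_start_s
  tt <- tr$time_s[on] - tr$protocol$pulse_start_s
  pred <- tr$current[on][1] * exp(-tr$k_obs * tt)
  expect_lt(max(abs(tr$current[on] - pred)), 1e-10)

  # recovery amplitudes are 1 - exp(-K_off t)
  pr <- patch_protocol(mode = "peak_recovery", concentration_uM = 100,
                       wash_intervals_s = c(0.5, 1, 2, 4, 8))
  rec <- simulate_patch_clamp(rates, pr)
  expect_equal(rec$amplitudes, 1 - exp(-0.55 * c(0.5, 1, 2, 4, 8)),
               tolerance = 1e-12)

  expect_error(patch_protocol(concentration_uM = -1), ">= 0")
  expect_error(patch_protocol(mode = "nonsense"), "unknown protocol mode")

  # trace IO round trip (delimited text + YAML sidecar)
  path <- file.path(withr::local_tempdir(), "trace.tsv")
  write_current_trace(tr, path)
  back <- read_current_trace(path)
  expect_equal(back$current, tr$current, tolerance = 1e-6)
  expect_equal(back$protocol$concentration_uM, 1e6)
})

test_that("analytic surfaces invert the potential exactly", {
  # single well: minimum (G = 0) at its centre
  pot1 <- potential_spec(list(list(center = c(0.5, -0.2), depth = 5,
                                   width = 0.4)), confinement = 0.5,
                         kT = kT310)
  s1 <- analytic_surface(pot1, n_bins = 81)
  i <- which(s1$G == 0, arr.ind = TRUE)
  expect_lt(abs(s1$x_centers[i[1]] - 0.5), 0.05)
  expect_lt(abs(s1$y_centers[i[2]] + 0.2), 0.05)

  # two well-separated equal-width wells, depths 10 and 8, no confinement:
  # dG between the minima bins = 2 kJ/mol
  pot2 <- potential_spec(list(list(center = c(-3, 0), depth = 10, width = 0.3),
                              list(center = c(3, 0), depth = 8, width = 0.3)),
                         confinement = 0, kT = kT310)
  s2 <- analytic_surface(pot2, n_bins = 301)
  gmin_right <- min(s2$G[s2$x_centers > 0, ])
  expect_equal(gmin_right, 2, tolerance = 0.02)

  # refinement: halving the bin size changes per-bin G by < 0.1 kJ/mol for
  # a gentle potential (compare nearest centres)
  gentle <- potential_spec(list(list(center = c(0, 0), depth = 3, width = 1)),
                           confinement = 0.5, kT = kT310)
  gc_ <- analytic_surface(gentle, n_bins = 50)
  gf <- analytic_surface(gentle, n_bins = 100)
  # block-average the refined surface back onto the coarse bins: for a
  # smooth potential the surfaces agree within 0.1 kJ/mol
  blk <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    blk[i, j] <- mean(gf$G[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_lt(max(abs(blk - gc_$G)), 0.1)

  # custom grid must cover the wells
  expect_error(analytic_surface(pot1, grid = list(x = 0:1, y = 0:1)),
               "must cover")
})

test_that("feature tables round-trip through tab-delimited text", {
  ft <- feature_table(c(0, 0.5, 1), a_nm = c(1, 2, 3), e_kjmol = c(-1, -2, -3))
  path <- file.path(withr::local_tempdir(), "ft.tsv")
  write_feature_table(ft, path)
  expect_identical(readLines(path)[1], "time_ns\ta_nm\te_kjmol")
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12)
  expect_equal(frame_stride(back), 0.5)
  expect_error(feature_table(c(0, 0, 1), a = 1:3), "strictly increasing")
  expect_error(feature_table(c(0, 1), a = 1:3), "length mismatch")
})
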