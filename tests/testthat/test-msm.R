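test_that("tICA reduces to autocorrelation in 1-D and unmixes OU processes", {
  # single feature: lambda1 equals the lag-tau autocorrelation
  x <- ou_series(5000, tr = 30, seed = 3)
  m1 <- fit_tica(list(matrix(x)), lag_ns = 2.5, dt_ns = 0.5)  # lag 5 steps
  xc <- x - mean(x)
  ac5 <- sum(xc[1:(5000 - 5)] * xc[6:5000]) / sum(xc^2)
  expect_equal(m1$eigenvalues[1], ac5, tolerance = 0.02)

  # OU eigenvalue ~ exp(-tau / t_relax)
  xo <- ou_series(40000, tr = 50, seed = 4)
  mo <- fit_tica(list(matrix(xo)), lag_ns = 5, dt_ns = 0.5)  # lag 10 steps
  expect_equal(mo$eigenvalues[1], exp(-10 / 50), tolerance = 0.05)

  # known rotation of a slow and a fast OU process: IC1 recovers the slow one
  slow <- ou_series(20000, tr = 100, seed = 5)
  fast <- ou_series(20000, tr = 10, seed = 6)
  th <- pi / 6
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  X <- cbind(slow, fast) %*% t(R)
  mt <- fit_tica(list(X), lag_ns = 5, dt_ns = 0.5)
  pr <- tica_project(mt, X)
  expect_gte(abs(cor(pr[, 1], slow)), 0.9)
  expect_lte(max(mt$eigenvalues), 1 + 1e-6)

  # trajectories shorter than the lag are skipped; all skipped is an error
  expect_warning(fit_tica(list(X, X[1:5, ]), lag_ns = 5, dt_ns = 0.5),
                 "skipped")
  expect_error(suppressWarnings(fit_tica(list(X[1:5, ]), lag_ns = 5,
                                         dt_ns = 0.5)), "no trajectory")
  expect_error(fit_tica(list(X), lag_ns = 5.3, dt_ns = 0.5), "multiple")

  # all conditions share one basis: the model hash is stable
  expect_identical(mt$hash, fit_tica(list(X), lag_ns = 5, dt_ns = 0.5)$hash)
})

test_that("k-means discretization is exact, accurate and deterministic", {
  # distinct points, k = n: zero inertia
  withr::with_seed(20, P <- matrix(rnorm(20), 10, 2))
  d0 <- discretize(P, k = 10, seed = 1)
  expect_equal(d0$inertia, 0, tolerance = 1e-12)

  # two well-separated blobs: centres within 3 SE of the blob means
  withr::with_seed(21, {
    b1 <- matrix(rnorm(4000, sd = 0.5), ncol = 2)
    b2 <- sweep(matrix(rnorm(4000, sd = 0.5), ncol = 2), 2L, c(10, 10), `+`)
  })
  db <- discretize(rbind(b1, b2), k = 2, seed = 2)
  cen <- db$centers[order(db$centers[, 1]), ]
  se3 <- 3 * 0.5 / sqrt(2000)
  expect_lt(max(abs(cen[1, ] - colMeans(b1))), se3)
  expect_lt(max(abs(cen[2, ] - colMeans(b2))), se3)

  # determinism and state assignment bounds
  db2 <- discretize(rbind(b1, b2), k = 2, seed = 2)
  expect_identical(db$dtrajs, db2$dtrajs)
  expect_true(all(unlist(db$dtrajs) %in% 0:1))
  expect_error(discretize(P, k = 11), "exceeds")

  # assigning new points uses nearest centres
  expect_equal(assign_states(db, matrix(c(0, 0, 10, 10), 2, byrow = TRUE)),
               order(db$centers[, 1]) - 1L)
})

test_that("MSM estimation is reversible, consistent and handles disconnects", {
  # symmetric counts: exact closed form
  d <- c(0L, 0L, 1L, 1L, 0L)
  C <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  fit <- gatekin:::reversible_mle_cpp(C, 1e-12, 1e5)
  expect_equal(fit$T, matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE),
               tolerance = 1e-10)
  expect_equal(as.numeric(fit$pi), c(0.5, 0.5), tolerance = 1e-10)

  # simulated 3-state chain: invariants of the reversible estimate
  oc <- oracle_chain()
  dt <- simulate_discrete_chain(oc$P, 3e4, seed = 9)
  m <- estimate_msm(dt, lag_ns = 0.5, dt_ns = 0.5)
  expect_equal(rowSums(m$T), rep(1, 3), tolerance = 1e-10)
  expect_equal(as.numeric(m$pi %*% m$T), m$pi, tolerance = 1e-8)
  flux <- m$pi * m$T
  expect_lt(max(abs(flux - t(flux))), 1e-8)          # detailed balance
  expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
  expect_true(all(abs(Im(m$eigenvalues)) == 0))

  # disconnected blocks: larger block kept, dropped states named
  dtr <- list(rep(c(0L, 1L, 2L), 100), rep(c(3L, 4L), 30))
  expect_warning(md <- estimate_msm(dtr, lag_ns = 0.5, dt_ns = 0.5),
                 "dropped: 3, 4")
  expect_equal(md$active, 0:2)
  expect_error(suppressWarnings(
    estimate_msm(list(rep(0L, 50)), lag_ns = 0.5, dt_ns = 0.5)),
    ">= 2 states")
  # non-reversible option: plain row normalization
  mn <- estimate_msm(dt, lag_ns = 0.5, dt_ns = 0.5, reversible = FALSE)
  expect_equal(rowSums(mn$T), rep(1, 3), tolerance = 1e-12)
})

test_that("implied timescales follow -tau/log(lambda) and mask degeneracy", {
  # 2-state symmetric chain: lambda2 = 0.6 at one step; at lag 25 ns the
  # timescale is -25 / log 0.6 = 48.94 ns, flat across lag multiples
  P <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE)
  dt <- lapply(1:4, function(i) simulate_discrete_chain(P, 5e4, seed = 30 + i))
  its <- implied_timescales(dt, lags_ns = c(25, 50, 75), n_timescales = 1,
                            dt_ns = 25)
  truth <- -25 / log(0.6)
  expect_equal(truth, 48.94, tolerance = 1e-3)
  expect_lt(max(abs(its$its_ns / truth - 1)), 0.1)

  # eigenvalue outside (0, 1): masked, not clamped to infinity (a strictly
  # period-2 chain has lambda2 = -1)
  dts <- list(rep(c(0L, 1L), 150))
  itm <- implied_timescales(dts, lags_ns = 25, n_timescales = 1, dt_ns = 25)
  expect_true(is.na(itm$its_ns[1]))

  expect_error(implied_timescales(dt, lags_ns = 5e4 * 25, dt_ns = 25),
               "not shorter")
})

test_that("Chapman-Kolmogorov factor 1 is an exact identity", {
  oc <- oracle_chain()
  dt <- lapply(1:5, function(i) simulate_discrete_chain(oc$P, 5000, seed = 40 + i))
  m <- estimate_msm(dt, lag_ns = 0.5, dt_ns = 0.5)
  ck <- ck_test(m, dt, factors = 1:2, n_boot = 5, seed = 1)
  f1 <- ck[ck$factor == 1, ]
  expect_equal(f1$predicted, f1$estimated, tolerance = 1e-12)
  expect_true(all(ck$predicted >= 0 & ck$predicted <= 1))
  expect_warning(ck_test(m, dt, factors = c(1, 10^4), n_boot = 2, seed = 1),
                 "dropped")
})

test_that("free-energy surfaces implement the stationary-weight log rule", {
  # hand-built two-state model: pi = (0.8, 0.2) in separate bins
  fake_disc <- structure(list(centers = rbind(c(-1, 0), c(1, 0)), k = 2,
                              dtrajs = list(c(0L, 1L)), seed = 1),
                         class = "discretization")
  fake_msm <- structure(list(T = diag(2), pi = c(0.8, 0.2), active = 0:1),
                        class = "msm_model")
  grid <- list(x = c(-2, 0, 2), y = c(-1, 1))
  s <- free_energy_surface(fake_msm, fake_disc, grid = grid,
                           method = "centers")
  # dG = kT ln 4 = 3.573 kJ/mol at 310 K
  expect_equal(s$G[2, 1] - s$G[1, 1], 2.5775 * log(4), tolerance = 1e-3)
  expect_equal(min(s$G[s$occupied]), 0)

  # equal masses: dG = 0
  fm2 <- fake_msm; fm2$pi <- c(0.5, 0.5)
  s2 <- free_energy_surface(fm2, fake_disc, grid = grid, method = "centers")
  expect_equal(s2$G[1, 1], s2$G[2, 1])

  # two microstates mapped to one bin sum their weights
  fd3 <- fake_disc; fd3$centers <- rbind(c(-1, 0), c(-0.5, 0))
  fm3 <- fake_msm; fm3$pi <- c(0.3, 0.2)
  s3 <- free_energy_surface(fm3, fd3, grid = grid, method = "centers")
  expect_equal(s3$weight[1, 1], 0.5)

  # all mass in one bin: valid single zero-energy bin
  fd4 <- fake_disc; fd4$centers <- rbind(c(-1, 0), c(-1.1, 0))
  s4 <- free_energy_surface(fake_msm, fd4, grid = grid, method = "centers")
  expect_equal(sum(s4$occupied), 1L)
  expect_equal(s4$G[s4$occupied], 0)
})

test_that("bootstrap surfaces are degenerate for identical input", {
  oc <- oracle_chain()
  d1 <- simulate_discrete_chain(oc$P, 4000, seed = 50)
  # project states onto a fake 2-D layout so surfaces can be binned
  centers <- rbind(c(-1, 0), c(0, 0), c(1, 0))
  proj <- centers[d1 + 1L, ]
  disc <- structure(list(centers = centers, dtrajs = list(d1, d1),
                         projections = list(proj, proj), k = 3, seed = 1),
                    class = "discretization")
  bs <- bootstrap_surface(disc, lag_ns = 0.5, dt_ns = 0.5,
                          grid = list(x = seq(-1.5, 1.5, length.out = 4),
                                      y = c(-1, 1)),
                          n_boot = 5, seed = 2)
  expect_equal(max(bs$sd$G[bs$sd$occupied]), 0, tolerance = 1e-6)
  expect_true(all(bs$sd$G[bs$sd$occupied] >= 0))
  expect_error(bootstrap_surface(disc, n_boot = 1), "n_boot")
})

test_that("analysis tables serialize with '#' metadata headers", {
  pot <- two_basin_potential(2)
  s <- analytic_surface(pot, n_bins = 10)
  path <- file.path(withr::local_tempdir(), "fes.tsv")
  write_analysis_table(s, path, meta = list(seed = 1))
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "# type: free_energy_surface"))
  expect_true(any(grepl("^# seed: 1", lines)))
  body <- read.delim(path, comment.char = "#")
  expect_equal(nrow(body), 100L)
})
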