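# fixtures are built in code: no binary files, everything seeded

kT310 <- kT_kjmol(310)

# minimal PDB text builder (fixed-column ATOM records, coordinates in Angstrom)
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          occ = 1.00, altloc = " ", element = "C",
                          record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resid, x, y, z,
          occ, 0.0, element)
}

make_pdb_text <- function(lines) paste(c(lines, "END"), collapse = "\n")

# a 4-residue CA-only chain along z, one atom per residue
simple_ca_model <- function(z = c(0, 10, 20, 30), chain = "A") {
  lines <- vapply(seq_along(z), function(i)
    pdb_atom_line(i, "CA", "ALA", chain, i, 0, 0, z[i]), "")
  read_structure(make_pdb_text(lines))
}

# an Ornstein-Uhlenbeck series with relaxation time tr (in steps)
ou_series <- function(n, tr, seed) {
  withr::with_seed(seed, {
    a <- exp(-1 / tr)
    x <- numeric(n)
    x[1] <- rnorm(1)
    for (t in 2:n) x[t] <- a * x[t - 1] + sqrt(1 - a^2) * rnorm(1)
    x
  })
}

# detailed-balance 3-state chain used as the MSM oracle throughout
oracle_chain <- function() {
  W <- matrix(c(8, 1.5, 0.5,
                1.5, 6, 0.5,
                0.5, 0.5, 4), 3, 3, byrow = TRUE)
  P <- W / rowSums(W)
  list(P = P, pi = rowSums(W) / sum(W),
       lambda = sort(Re(eigen(P)$values), decreasing = TRUE))
}

# fine Boltzmann quadrature of a 2-D potential: basin-occupancy ratio of
# the occluded (x < 0) vs outward-open (x > 0) side -- the independent
# oracle for the Langevin equilibrium tests
boltzmann_ratio <- function(pot, xlim = c(-5, 5.5), ylim = c(-2.8, 2.8),
                            n = c(1201, 801)) {
  xs <- seq(xlim[1], xlim[2], length.out = n[1])
  ys <- seq(ylim[1], ylim[2], length.out = n[2])
  pts <- cbind(rep(xs, times = n[2]), rep(ys, each = n[1]))
  w <- exp(-potential_energy(pot, pts) / pot$kT)
  sum(w[pts[, 1] < 0]) / sum(w[pts[, 1] > 0])
}

# empirical free-energy histogram of latent coordinates on a surface grid
empirical_surface_error <- function(coords, ref, weight_min = 1e-3) {
  nx <- length(ref$x_centers)
  ny <- length(ref$y_centers)
  ix <- findInterval(coords[, 1], ref$x_edges, rightmost.closed = TRUE)
  iy <- findInterval(coords[, 2], ref$y_edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  W <- matrix(0, nx, ny)
  acc <- rowsum(rep(1, sum(ok)), (iy[ok] - 1L) * nx + ix[ok])
  W[as.integer(rownames(acc))] <- acc
  W <- W / sum(W)
  m <- W > weight_min
  Gs <- -ref$kT * log(W)
  a <- Gs - min(Gs[m])
  b <- ref$G - min(ref$G[m])
  max(abs(a[m] - b[m])) / ref$kT
}
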