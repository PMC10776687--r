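test_that("PDB parsing converts units and resolves models and altlocs", {
  m <- read_structure(make_pdb_text(pdb_atom_line(1, "CA", "GLY", "A", 1,
                                                  10, 0, 0)))
  expect_equal(m$frames[[1]][1, ], c(1, 0, 0), ignore_attr = TRUE)

  two <- make_pdb_text(c("MODEL        1",
                         pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                         pdb_atom_line(2, "CA", "GLY", "A", 2, 0, 0, 5),
                         "ENDMDL", "MODEL        2",
                         pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 1),
                         pdb_atom_line(2, "CA", "GLY", "A", 2, 0, 0, 6),
                         "ENDMDL"))
  m2 <- read_structure(two)
  expect_length(m2$frames, 2L)
  expect_equal(nrow(m2$atoms), 2L)
  expect_equal(m2$frames[[2]][1, 3], 0.1)

  alt <- make_pdb_text(c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.6, altloc = "A"),
    pdb_atom_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.4, altloc = "B")))
  ma <- read_structure(alt)
  expect_equal(nrow(ma$atoms), 1L)
  expect_equal(ma$frames[[1]][1, 1], 0)   # higher occupancy retained
  tie <- make_pdb_text(c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.5, altloc = "B"),
    pdb_atom_line(2, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.5, altloc = "A")))
  expect_equal(read_structure(tie)$frames[[1]][1, 1], 0)  # tie goes to 'A'

  bad <- make_pdb_text(c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                         "ATOM      2  CA  GLY A   2      xx.xxx   0.000   0.000  1.00  0.00           C"))
  expect_error(read_structure(bad), "line 2")
  expect_error(read_structure("REMARK nothing here"), "no ATOM")
})

test_that("centre-of-mass distances obey hand arithmetic and invariances", {
  # two-atom selection {(0,0,0),(0,0,2)} vs single atom (0,1,1): centroid
  # (0,0,1) -> distance 1.0 (coordinates here in Angstrom: 0,0,20 etc.)
  m <- read_structure(make_pdb_text(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 0, 0, 20),
    pdb_atom_line(3, "CA", "GLY", "A", 3, 0, 10, 10))))
  a <- selection_spec(1, 2)
  b <- selection_spec(3, 3)
  expect_equal(com_distance(m, a, b), 1.0, tolerance = 1e-12)
  expect_equal(com_distance(m, a, a), 0.0)
  # symmetric in its selections
  expect_equal(com_distance(m, a, b), com_distance(m, b, a))

  # invariant under global rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  m2$frames[[1]] <- sweep(m$frames[[1]] %*% t(R), 2L, c(1, -2, 3), `+`)
  expect_equal(com_distance(m2, a, b), com_distance(m, a, b),
               tolerance = 1e-12)

  expect_error(com_distance(m, selection_spec(50, 60), b), "empty")
  # single-atom CA selections: mass weighting is a no-op
  expect_equal(com_distance(m, a, b, mass_weighted = FALSE),
               com_distance(m, a, b), tolerance = 1e-12)
})

test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(31)
  z <- runif(6, 0, 30)
  ref <- simple_ca_model(z = z)
  ref$frames[[1]] <- ref$frames[[1]] + matrix(rnorm(18, sd = 0.3), 6, 3)
  sel <- selection_spec(1, 6)

  fit0 <- superpose_kabsch(ref, ref, sel)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  shifted <- ref
  shifted$frames[[1]] <- sweep(ref$frames[[1]], 2L, c(0.5, -1, 2), `+`)
  expect_equal(superpose_kabsch(shifted, ref, sel)$rmsd, 0, tolerance = 1e-12)

  # 90 degrees about z plus perturbation: rotation recovered, RMSD equals an
  # independent numerical-optimization oracle over rotation angles
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  pert <- matrix(rnorm(18, sd = 0.05), 6, 3)
  mob <- ref
  mob$frames[[1]] <- (ref$frames[[1]] + pert) %*% t(Rz)
  fit <- superpose_kabsch(mob, ref, sel)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  rmsd_at <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    P <- sweep(mob$frames[[1]], 2L, colMeans(mob$frames[[1]]))
    Q <- sweep(ref$frames[[1]], 2L, colMeans(ref$frames[[1]]))
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  oracle <- optim(c(0, 0, -pi / 2), rmsd_at,
                  method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))$value
  expect_equal(fit$rmsd, oracle, tolerance = 1e-6)
  # superposition never increases the RMSD over raw coordinates
  raw <- sqrt(mean(rowSums((mob$frames[[1]] - ref$frames[[1]])^2)))
  expect_lte(fit$rmsd, raw)

  mob2 <- simple_ca_model(z = c(0, 10, 20))
  expect_error(superpose_kabsch(mob2, ref, sel), "differ in atom count")
})

test_that("nonbonded energies follow the truncated Coulomb + LJ form", {
  p1 <- data.frame(charge = 1, sigma = 0, epsilon = 0)
  # +1e / +1e at 0.5 nm -> 138.935485 / 0.5 kJ/mol
  expect_equal(nonbonded_energy(c(0, 0, 0), p1, c(0.5, 0, 0), p1),
               277.87097, tolerance = 1e-5)
  # beyond the 0.9 nm cutoff: plain truncation to zero
  pm <- data.frame(charge = -1, sigma = 0, epsilon = 0)
  expect_equal(nonbonded_energy(c(0, 0, 0), p1, c(1, 0, 0), pm), 0)
  # LJ zero crossing at r = sigma_ij
  lj <- data.frame(charge = 0, sigma = 0.3, epsilon = 0.5)
  expect_equal(nonbonded_energy(c(0, 0, 0), lj, c(0.3, 0, 0), lj), 0,
               tolerance = 1e-12)

  # additive over disjoint residue subsets and symmetric under group swap
  set.seed(5)
  lig <- matrix(runif(9, 0, 0.5), 3)
  res <- matrix(runif(12, 0.2, 0.8), 4)
  pl <- data.frame(charge = rnorm(3, 0, 0.3), sigma = runif(3, 0.25, 0.35),
                   epsilon = runif(3, 0.1, 0.6))
  pr <- data.frame(charge = rnorm(4, 0, 0.3), sigma = runif(4, 0.25, 0.35),
                   epsilon = runif(4, 0.1, 0.6))
  whole <- suppressWarnings(nonbonded_energy(lig, pl, res, pr))
  parts <- suppressWarnings(
    nonbonded_energy(lig, pl, res[1:2, ], pr[1:2, ]) +
      nonbonded_energy(lig, pl, res[3:4, , drop = FALSE], pr[3:4, ]))
  expect_equal(whole, parts, tolerance = 1e-10)
  expect_equal(whole, suppressWarnings(nonbonded_energy(res, pr, lig, pl)),
               tolerance = 1e-10)

  expect_warning(nonbonded_energy(c(0, 0, 0), p1, c(0.01, 0, 0), pm),
                 "clash")
})

test_that("occlusion labelling partitions frames into the stated bands", {
  ref <- gate_reference(OO = 1.75, OC = 1.35)
  lab <- label_occlusion(c(1.35, 1.75, 1.55), ref)
  expect_equal(as.character(lab$labels), c("full", "none", "partial"))

  # every frame gets exactly one label for arbitrary inputs
  withr::with_seed(2, {
    d <- runif(500, 1.0, 2.0)
    l <- label_occlusion(d, ref)
    expect_false(any(is.na(l$labels)))
    expect_length(l$labels, 500)
  })
  expect_error(label_occlusion(1.5, ref, margin = 0.3), "margin")
  expect_error(gate_reference(OO = 1.3, OC = 1.4), "OO > OC")
})

test_that("interaction splitting applies the -20 kJ/mol rule", {
  ft <- feature_table(0:2 * 0.5, e_f335_kjmol = c(-30, -30, -30),
                      tm6a_tm9up_nm = c(1.4, 1.4, 1.4))
  sp <- split_by_interaction(ft)
  expect_equal(nrow(sp$weak), 0L)
  expect_equal(nrow(sp$strong), 3L)

  ft2 <- feature_table(c(0, 0.5), e_f335_kjmol = c(-30, -10),
                       tm6a_tm9up_nm = c(1.4, 1.7))
  sp2 <- split_by_interaction(ft2)
  expect_equal(nrow(sp2$strong), 1L)
  expect_equal(nrow(sp2$weak), 1L)
  # exactly at the threshold -> weak (strict inequality defines "strong")
  ft3 <- feature_table(c(0, 0.5), e_f335_kjmol = c(-20, -20.0001),
                       tm6a_tm9up_nm = c(1.5, 1.5))
  sp3 <- split_by_interaction(ft3)
  expect_equal(nrow(sp3$weak), 1L)
  expect_equal(nrow(sp3$strong), 1L)
  # histograms share bin edges
  expect_identical(sp2$histograms$breaks, sp2$histograms$breaks)
  expect_equal(sum(sp2$histograms$strong) + sum(sp2$histograms$weak), 2)

  # strongly interacting frames of a substrate ensemble are more occluded
  prof <- default_ligand_profiles()[["5HT"]]
  ens <- make_ligand_ensemble(prof, n_replicas = 3, n_steps = 20000, seed = 51)
  sp5 <- split_by_interaction(ens)
  expect_lt(mean(sp5$strong$tm6a_tm9up_nm), mean(sp5$weak$tm6a_tm9up_nm))

  expect_error(split_by_interaction(list()), "no input")
  expect_error(split_by_interaction(ft, energy_column = "missing"), "missing")
})

test_that("gate-distance series over multi-model files", {
  two <- make_pdb_text(c("MODEL        1",
                         pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                         pdb_atom_line(2, "CA", "GLY", "A", 5, 0, 0, 17.5),
                         "ENDMDL", "MODEL        2",
                         pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                         pdb_atom_line(2, "CA", "GLY", "A", 5, 0, 0, 13.5),
                         "ENDMDL"))
  m <- read_structure(two)
  ft <- gate_distance_series(m, list(tm6a_tm9up_nm = list(
    a = selection_spec(1, 1), b = selection_spec(5, 5))), dt_ns = 2)
  expect_equal(ft$tm6a_tm9up_nm, c(1.75, 1.35), tolerance = 1e-12)
  expect_equal(ft$time_ns, c(0, 2))
})
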