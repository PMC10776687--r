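#' Pairwise nonbonded interaction energy (Coulomb + Lennard-Jones)
#'
#' Analysis descriptor for the ligand-residue interaction strength (e.g.
#' compound vs F335 or D98): the sum over atom pairs within the cutoff of
#' \deqn{f q_i q_j / r + 4\epsilon_{ij}((\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6)}
#' with Lorentz-Berthelot combination rules (arithmetic-mean sigma,
#' geometric-mean epsilon) and plain truncation at the cutoff. This is a
#' descriptor, not a dynamics force, so no switching function is applied.
#'
#' @param pos_a,pos_b n x 3 coordinate matrices, nm
#' @param params_a,params_b data.frame per group with columns `charge` (e),
#'   `sigma` (nm), `epsilon` (kJ/mol)
#' @param cutoff truncation radius, nm (default 0.9)
#' @return interaction energy, kJ/mol
#' @export
nonbonded_energy <- function(pos_a, params_a, pos_b, params_b, cutoff = 0.9) {
  f <- 138.935485  # Coulomb prefactor, kJ mol^-1 nm e^-2
  pos_a <- rbind(pos_a)
  pos_b <- rbind(pos_b)
  check_params <- function(p, n, lab) {
    if (!all(c("charge", "sigma", "epsilon") %in% names(p)))
      stopf("%s params need charge, sigma, epsilon columns", lab)
    if (nrow(p) != n) stopf("%s params do not match atom count", lab)
    if (any(p$sigma < 0) || any(p$epsilon < 0))
      stopf("sigma and epsilon must be >= 0")
  }
  check_params(params_a, nrow(pos_a), "group a")
  check_params(params_b, nrow(pos_b), "group b")
  if (cutoff <= 0) stopf("cutoff must be > 0")

  # all pair distances (groups are residue-sized; dense evaluation is fine)
  d2 <- outer(rowSums(pos_a^2), rowSums(pos_b^2), `+`) -
    2 * pos_a %*% t(pos_b)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 0.05))
    warnf("atomic clash: %d pair(s) closer than 0.05 nm", sum(r < 0.05))
  qq <- outer(params_a$charge, params_b$charge)
  sig <- outer(params_a$sigma, params_b$sigma, `+`) / 2
  eps <- sqrt(outer(params_a$epsilon, params_b$epsilon))
  within <- r <= cutoff & r > 0
  sr6 <- (sig[within] / r[within])^6
  sum(f * qq[within] / r[within] + 4 * eps[within] * (sr6^2 - sr6))
}
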