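#' Centre-of-mass distance between two selections
#'
#' The occlusion observable: Euclidean distance between the (mass-weighted)
#' centroids of two helix segments, e.g. TM6a (G324-L337) to TM9up
#' (F475-S477) for the outer gate.
#'
#' @param model structure_model
#' @param a,b selection_spec for the two groups
#' @param frame frame index (default 1)
#' @param mass_weighted use atomic masses (default TRUE); for CA-only
#'   selections the unweighted centroid is numerically indistinguishable
#' @return distance in nm
#' @export
com_distance <- function(model, a, b, frame = 1L, mass_weighted = TRUE) {
  ia <- select_atoms(model, a)
  ib <- select_atoms(model, b)
  if (!length(ia)) stopf("selection `a` (%d-%d) is empty", a$first, a$last)
  if (!length(ib)) stopf("selection `b` (%d-%d) is empty", b$first, b$last)
  X <- model$frames[[frame]]
  centroid <- function(idx) {
    w <- if (mass_weighted) atom_masses(model$atoms$element[idx]) else rep(1, length(idx))
    colSums(X[idx, , drop = FALSE] * w) / sum(w)
  }
  sqrt(sum((centroid(ia) - centroid(ib))^2))
}

#' Gate-distance time series over a multi-model trajectory
#'
#' @param model structure_model with >= 1 frames
#' @param pairs named list of `list(a = selection_spec, b = selection_spec)`
#' @param dt_ns frame spacing, ns
#' @inheritParams com_distance
#' @return feature_table of distances (nm)
#' @export
gate_distance_series <- function(model, pairs, dt_ns = 1, mass_weighted = TRUE) {
  n <- length(model$frames)
  cols <- lapply(pairs, function(p)
    vapply(seq_len(n), function(f)
      com_distance(model, p$a, p$b, frame = f, mass_weighted = mass_weighted), 1.0))
  feature_table(seq(0, by = dt_ns, length.out = n), cols)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of a frame onto a reference over a fitting selection
#' (typically the C-alpha atoms of the transmembrane helices), excluding
#' reflections, with the RMSD over the fit selection.
#'
#' @param model structure_model (mobile)
#' @param reference structure_model
#' @param fit_selection selection_spec evaluated on both structures; the two
#'   selections must contain the same number of atoms
#' @param frame,ref_frame frame indices
#' @return list: `coords` (all atoms of `frame`, superposed), `rotation`
#'   (3 x 3, det = +1), `translation`, `rmsd` (nm, over the fit selection)
#' @export
superpose_kabsch <- function(model, reference, fit_selection,
                             frame = 1L, ref_frame = 1L) {
  im <- select_atoms(model, fit_selection)
  ir <- select_atoms(reference, fit_selection)
  if (length(im) != length(ir))
    stopf("fit selections differ in atom count: %d (mobile) vs %d (reference)",
          length(im), length(ir))
  if (length(im) < 3L) stopf("need >= 3 atoms to superpose")
  X <- model$frames[[frame]]
  P <- X[im, , drop = FALSE]
  Q <- reference$frames[[ref_frame]][ir, , drop = FALSE]
  pc <- colMeans(P)
  qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, pc), sweep(Q, 2L, qc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rotate <- function(M) sweep(sweep(M, 2L, pc) %*% t(R), 2L, qc, `+`)
  fitted <- rotate(P)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(coords = rotate(X), rotation = R,
       translation = qc - as.numeric(R %*% pc), rmsd = rmsd)
}
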