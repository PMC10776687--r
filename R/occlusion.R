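#' Structure-derived gate-distance references
#'
#' Reference values of a gate distance in the outward-open (OO), occluded
#' (OC) and inward-open (IO) conformations, either computed from reference
#' structures with [com_distance()] or configured. The outer-gate ordering
#' OO > OC is enforced.
#'
#' @param OO,OC,IO reference distances, nm (IO optional)
#' @param provenance "configured" or "computed"
#' @return object of class `gate_reference`
#' @export
gate_reference <- function(OO, OC, IO = NA_real_, provenance = "configured") {
  if (!is.finite(OO) || !is.finite(OC)) stopf("OO and OC must be finite")
  if (OO <= OC) stopf("outer-gate reference must satisfy OO > OC (got OO = %g, OC = %g)", OO, OC)
  structure(list(OO = OO, OC = OC, IO = IO, provenance = provenance),
            class = "gate_reference")
}

#' Classify frames by degree of occlusion
#'
#' Bands a gate-distance series against its structural references: `full`
#' occlusion at or below the occluded reference (+ margin), `none` at or
#' above the outward-open reference (- margin), `partial` in between. Every
#' frame receives exactly one label.
#'
#' @param distance_nm numeric vector of gate distances
#' @param ref gate_reference
#' @param margin band half-width, nm (default 0.05); must be smaller than
#'   half the OO-OC separation or the bands would overlap
#' @return object of class `occlusion_labels`: factor with levels
#'   none/partial/full plus the thresholds used
#' @export
label_occlusion <- function(distance_nm, ref, margin = 0.05) {
  stopifnot(inherits(ref, "gate_reference"))
  if (margin >= (ref$OO - ref$OC) / 2)
    stopf("margin (%g) must be < half the OO-OC separation (%g)",
          margin, (ref$OO - ref$OC) / 2)
  lab <- ifelse(distance_nm <= ref$OC + margin, "full",
                ifelse(distance_nm >= ref$OO - margin, "none", "partial"))
  structure(list(labels = factor(lab, levels = c("none", "partial", "full")),
                 ref = ref, margin = margin),
            class = "occlusion_labels")
}

#' Split frames by ligand-residue interaction strength
#'
#' Pools feature tables and separates frames into strongly interacting
#' (energy < threshold) and weakly interacting (energy >= threshold)
#' conformations; the default threshold of -20 kJ/mol is the canonical split
#' between the weakly and strongly interacting populations. Frames exactly
#' at the threshold go to the weak set ("strong" is a strict inequality).
#' Distance histograms for each set share common bin edges so the two
#' populations are directly comparable.
#'
#' @param tables list of feature_table (or a single one)
#' @param energy_column name of the interaction-energy column
#' @param threshold kJ/mol, default -20
#' @param distance_column column to histogram (default `tm6a_tm9up_nm`)
#' @param n_bins histogram bins
#' @return list: `strong` and `weak` (pooled data.frames), `histograms`
#'   (shared `breaks`, per-set `counts`), `threshold`
#' @export
split_by_interaction <- function(tables, energy_column = "e_f335_kjmol",
                                 threshold = -20,
                                 distance_column = "tm6a_tm9up_nm",
                                 n_bins = 50L) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  if (!length(tables)) stopf("no input tables")
  for (tb in tables)
    if (!energy_column %in% names(tb))
      stopf("energy column '%s' missing from input", energy_column)
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  strong <- pooled[pooled[[energy_column]] < threshold, , drop = FALSE]
  weak <- pooled[pooled[[energy_column]] >= threshold, , drop = FALSE]
  hist_out <- NULL
  if (distance_column %in% names(pooled)) {
    rng <- range(pooled[[distance_column]])
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    cnt <- function(d) {
      if (!nrow(d)) return(rep(0L, n_bins))
      graphics::hist(d[[distance_column]], breaks = breaks, plot = FALSE)$counts
    }
    hist_out <- list(breaks = breaks, strong = cnt(strong), weak = cnt(weak))
  }
  list(strong = strong, weak = weak, histograms = hist_out,
       threshold = threshold, energy_column = energy_column)
}
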