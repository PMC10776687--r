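---
title: "Models and methods: transporter occlusion energetics and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: transporter occlusion energetics and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the parameters that matter, and
what a green test does — and does not — establish. All empirical numbers
quoted here are computed by the test suite or by `scripts/acceptance.R`;
nothing is asserted that the code does not itself measure.

## 1. The scientific problem

Neurotransmitter transporters of the SLC6 family alternate between an
outward-open (OO) state that binds extracellular substrate, an occluded
(OC) state in which the extracellular ("outer") gate has closed over the
bound ligand, and an inward-open (IO) state that releases substrate to the
cytosol. At least one gate is closed in every state. Whether a compound
*induces* occlusion after binding is the mechanistic watershed between a
transported substrate and an inhibitor that merely occupies the binding
site. The package quantifies this watershed twice over:

* structurally, through the free-energy balance between the OO and OC
  basins estimated from conformational ensembles, and
* kinetically, through the rate constants that electrophysiology resolves
  (flipping rate, K_on, K_off, cumulative K_off) and uptake assays resolve
  (IC50, Km, Vmax).

## 2. The synthetic world

Real inputs — microsecond atomistic trajectories, patch-clamp recordings —
cannot ship with a package. Instead, a generator produces data whose
ground truth is known exactly, so every estimator can be validated
end-to-end.

### 2.1 Latent occlusion dynamics

The conformational coordinate is a 2-D latent vector: axis 1 is the
occlusion progress (OO basin at positive values, OC at negative), axis 2 a
fast orthogonal mode included so that slowness-ordering methods (tICA)
have a nontrivial ordering to recover. The potential is a sum of inverted
Gaussian wells plus harmonic confinement,

$$U(x) = -\sum_w d_w\,e^{-\|x-c_w\|^2/2\sigma_w^2} + \kappa_c\|x\|^2 ,$$

integrated by overdamped Euler–Maruyama,
$x \leftarrow x - (D/k_BT)\nabla U\,\Delta t + \sqrt{2D\Delta t}\,\xi$.
Euler–Maruyama (rather than BAOAB or similar) is sufficient because only
equilibrium statistics are asserted; the integrator's stationary bias
scales with $a = \kappa D \Delta t / k_BT$ (the per-step relaxation
fraction), and all defaults keep $a \le 0.09$ so the bias stays well below
the 0.3 kT tolerance of the recovery tests.

Two geometric decisions matter and were made once:

* **Constant well-bottom curvature.** Well widths are tied to depths,
  $\sigma_w = \sqrt{d_w/\kappa}$ with a common curvature $\kappa$
  (default 40 kJ mol⁻¹ unit⁻²). With equal curvature the harmonic
  prefactors of the basin partition functions cancel, so basin weights
  track the Boltzmann factor of the depth difference alone — the property
  the ligand profiles rely on to encode their occupancy ordering.
* **The `two_basin_potential` benchmark** creates a stated free-energy
  offset between two *congruent* wells through the confinement term (the
  occluded well sits at a smaller radius). The bin-level difference
  between the two minima is then exactly `delta_kT` × kT. Note that the
  *basin occupancy ratio* equals $e^{\Delta G/k_BT}$ only in the
  narrow-well idealization: at widths that still permit desk-scale
  barrier crossing, the confinement plateau between the wells and the
  anharmonic tails contribute tens of percent. The equilibrium tests
  therefore assert the simulated ratio against the direct Boltzmann
  quadrature of $e^{-U/k_BT}$ (the package's stated oracle), not against
  the idealized closed form.

### 2.2 Ligand profiles and emission

Each condition (apo, serotonin = 5HT, and its methyl / propyl / butyl
analogues M-5HT, P-5HT, B-5HT, plus cocaine) is a `ligand_profile` giving
the two well depths and the observable endpoints. The stock depths encode
the qualitative free-energy ordering the series exhibits: the OC basin
dominates for 5HT, OO and OC are of comparable depth for P-5HT, OO
dominates for B-5HT, and M-5HT and cocaine barely populate OC. Gate
distances and interaction energies are affine in the occlusion progress
between their OO and OC endpoints, plus i.i.d. Gaussian noise (default
0.02 nm for distances, 2 kJ/mol for energies).

Default endpoints: tm6a–tm9up 1.75 → 1.35 nm, tm1b–tm9up 1.45 → 1.10 nm
(outer gate closes); inner-gate distances D87–F268 0.80 → 1.00 nm,
D87–V281 0.90 → 1.15 nm, F268–Y289 0.55 → 0.75 nm (the inner gate loosens
as occlusion proceeds). The outer-gate numbers are stand-ins preserving
the OO > OC ordering of the structure-derived references — the source
structures' values are not bundled, and users holding the reference PDB
files can substitute computed values via `gate_reference(provenance =
"computed")`. Substrate profiles emit F335 interaction energies of −5
kJ/mol (OO) to −35 kJ/mol (OC), placing the conventional −20 kJ/mol
weak/strong split between the basins; the cocaine profile saturates at
−17 kJ/mol so its frames stay on the weak side.

What the generator does **not** emulate: force-field realism, gate
kinetics coupled to ion binding, multi-step translocation, emission
noise correlated across observables, or non-Markovian memory from
orthogonal degrees of freedom. A green recovery test therefore
establishes estimator correctness, not force-field or sampling adequacy
for any real system.

### 2.3 Patch-clamp traces

`simulate_patch_clamp` produces capacitive peak currents
$I(t) = A e^{-k_{obs}t}$ whose observed rate follows the saturating dose
law $k_{obs} = \mathrm{Plateau}\,(1-e^{-Kc})$ with
$\mathrm{Plateau} = k_{flip}$ and $K = K_{on}/k_{flip}$, so the
dose-curve's derivative at zero concentration is exactly K_on; recovery
trains scale successive pulse amplitudes by $1-e^{-K_{off}t_w}$. The
stock rate table uses the published point estimates for the serotonin
series as generation truth (flipping rates 104.30 / 32.06 / 72.30 /
50.05 s⁻¹; K_on 6.3 / 1.2 / 26.1 / 20.7 µM⁻¹s⁻¹; K_off 0.55 / 3.16 /
0.31 / 0.15 s⁻¹; cumulative K_off 0.24 / 0.04 / 0.03 s⁻¹ for the
analogues — serotonin's own cumulative rate is not separately resolved by
that protocol and defaults to its K_off; IC50 4.49 / 79.35 / 0.59 /
0.27 µM).

## 3. The estimation chain

**tICA.** Symmetrized instantaneous and time-lagged covariances pooled
over trajectories (lagged pairs never straddle trajectory boundaries),
ridge-regularized generalized eigenproblem, components ordered by
eigenvalue. Default lag 5 ns at 0.5 ns frame spacing. The model is fitted
once on the pooled all-condition dataset and every condition is projected
into that shared IC1/IC2 basis; the model hash is recorded so shared-basis
use can be asserted.

**Discretization.** k-means++ initialization under a fixed seed, Lloyd
iterations to a relative inertia change below 1e-6 (empty clusters
re-seeded from the farthest point). The default centre count is 500; the
iteration cap is configurable because on 10⁶-frame inputs Lloyd converges
numerically long before the strict tolerance is met (the test fixtures
cap at 40–60 iterations, which changes recovered surfaces by far less
than their statistical error).

**MSM.** Sliding-window transition counts at lag 25 ns (default),
restriction to the largest strongly connected component of the count
graph, and the reversible maximum-likelihood transition matrix via the
standard self-consistent iteration on symmetrized sufficient statistics,
converged at 1e-10. Eigenvalues are computed through the
$\pi$-symmetrized form, so they are exactly real for reversible
estimates. Validation: implied timescales $t_i = -\tau/\ln\lambda_i$
across lags (eigenvalues outside (0,1) masked, never clamped), and the
Chapman–Kolmogorov test on metastable sets from the sign structure of the
slow right eigenvectors, with trajectory-bootstrap error bars.

**Free-energy surfaces.** $G(S_i) = -k_BT\ln\sum_{j\in S_i}\pi_j$, shifted
to zero at the occupied minimum, 310 K. The default estimator spreads each
microstate's stationary weight evenly over its member frames and bins the
frames ("trajectory reweighting"). The alternative `method = "centers"`
assigns a microstate's whole weight to the bin holding its centre; it is
faithful only when microstates are much denser than bins, and measurably
quantizes the surface otherwise — with 200 microstates over ~160 occupied
bins it missed the oracle by >2 kT where frame weighting achieves
~0.2 kT. Both are the same stationary-weight rule at different
resolutions; frame weighting is the default for exactly this reason.

**Bootstrap.** Whole trajectories resampled with replacement; tICA and
cluster centres stay fixed from the full dataset so that all replicate
surfaces share one support and per-bin mean ± SD are well defined.

**Grid choice for oracle comparisons.** The recovery tests compare on a
100×100 grid rather than the plotting default of 50×50. The reason is a
sampling effect, not accuracy of the estimator: bins whose stationary
weight sits just above the 10⁻³ occupancy cutoff at the rim of a basin
are populated by a handful of long excursions, so their weight fluctuates
by whole visits (0.3–0.45 kT at 50 bins across seeds); on a finer grid the
same cutoff lands in continuously revisited territory and the comparison
reflects estimator error (~0.2 kT) rather than visit-count shot noise.

## 4. Collective modes

PCA is an eigendecomposition of the pooled covariance with a
deterministic largest-entry-positive sign convention. FMA is PLS1
(NIPALS): directions maximizing covariance with the query residual are
extracted and deflated; the reported mode is the regression-optimal
combination of the components. Deflation stops when the query residual is
numerically exhausted (keeping degenerate directions would contaminate
the regression vector). Trajectories are subsampled to 2000 equally
spaced frames (first and last always included); 10 components by default.
Validation splits are time-blocked (first half train, second half test)
to respect autocorrelation, since a random split would leak
autocorrelated frames across the split.

The mode-filtered trajectory is $\bar{x} + (x\cdot m)\,m$, and RMSF is
taken per residue over it. The bound "filtered RMSF ≤ unfiltered RMSF"
is exact for the population mode; an estimated mode redistributes a few
percent of amplitude between residues when the query is noisy (the test
suite measures ~4% on a planted case at 10% query noise and asserts the
bound with 10% slack, and exact equality on noiseless rank-1 data).

## 5. Kinetic fits

All fits run through one Levenberg–Marquardt core with numerically exact
initialization rules (peak minus tail for amplitude, time-to-37%-decay
for rates, half-response concentration for midpoints). `stats::nls` was
deliberately not used: the oracle tests require exact zero-residual data,
on which `nls` aborts. Confidence intervals are asymptotic
(t-quantile × SE from the residual Jacobian); a 200-seed calibration at
the published point estimates measures 93–97% empirical coverage for the
nominal 95% intervals, within the accepted [90%, 99%] band.

Decision rules: the IC50 fit fixes the Hill slope at 1 (the printed form
of the equation carries no slope; `hill_free = TRUE` frees it). Frames
exactly at the −20 kJ/mol interaction threshold are classed weak, because
"strong" is defined by strict inequality. Inhibition classification calls
Km "raised" / Vmax "lowered" when the treated/control ratio crosses 1.5
(default), and "unchanged" when the 95% CIs overlap; both-raised-and-
lowered yields "mixed". The numeric threshold is a package decision — the
qualitative hallmarks define the classes but no published numeric rule
exists.

## 6. Numerical choices and degenerate inputs

* Lengths in nm (PDB Å converted at parse time), energies kJ/mol,
  times ns (simulation) and s (electrophysiology), concentrations µM.
* Coulomb constant f = 138.935485 kJ mol⁻¹ nm e⁻²; Lorentz–Berthelot
  combination; plain truncation at 0.9 nm (a descriptor, not a dynamics
  force, so no switching function).
* Alternate locations: highest occupancy wins, ties go to altLoc "A".
* Eigenvector and mode signs: largest-magnitude entry positive.
* Replica seeds are master + index; emission streams are offset by
  500000 so trajectory and emission noise never share a stream. All
  randomness passes through `withr::with_seed`, so the caller's RNG state
  is untouched and byte-identical reruns are guaranteed.
* Degenerate inputs error early and informatively: non-stochastic
  matrices, empty selections, constant queries or traces, amplitudes at
  plateau (rate unidentifiable), margins that would overlap the occlusion
  bands, disconnected count graphs with no 2-state component.

## 7. Known limitations

* The latent occlusion model is two-state by construction; it cannot test
  detection of intermediate metastable states.
* CK-test macrostates come from eigenvector sign structure only; no
  PCCA+ or fuzzy memberships.
* Reversible estimation assumes equilibrium sampling within each
  condition; no TRAM/MBAR-style multi-ensemble estimators.
* The PDB reader covers fixed-column ATOM/HETATM/MODEL records
  sufficient for featurization — it is not a general structure parser
  (no insertion codes, no mmCIF).
* Asymptotic CIs are first-order; for very small designs (< 6 points)
  bootstrap CIs would be preferable and are not implemented.
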