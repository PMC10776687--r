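# gatekin

Conformational and kinetic signatures that separate transporter
**substrates** from **inhibitors**, implemented as a tested, reusable R
pipeline.

Secondary active neurotransmitter transporters such as the serotonin
transporter (SERT, SLC6A4) work by alternating access: the bundle domain
tilts toward the scaffold, closing the extracellular (outer) gate around
the bound ligand (occlusion), before the intracellular (inner) gate opens
and releases substrate and co-transported ions into the cytosol.
Substrates trigger this occlusion; inhibitors trap the transporter
outward-open. `gatekin` provides the computational machinery used to make
that distinction quantitative, for two kinds of data:

* **Structural ensembles / trajectories** — gate-distance featurization
  (e.g. centre-of-mass distance TM6a–TM9up for the outer vestibule,
  D87–F268 / D87–V281 / F268–Y289 for the inner gate), ligand–residue
  interaction energies (truncated Coulomb + Lennard-Jones at a 0.9 nm
  cutoff), occlusion labelling, principal component analysis, functional
  mode analysis (FMA) against an interaction-energy query with
  mode-filtered RMSF, and the full
  tICA → k-means → reversible Markov state model → free-energy-surface
  chain with implied-timescale, Chapman–Kolmogorov and bootstrap
  validation. Free energies follow the stationary-weight rule
  `G(S_i) = -k_B T ln Σ_{j∈S_i} π_j` (k_B·T = 2.5775 kJ/mol at 310 K).

* **Electrophysiology / uptake measurements** — the standard fit
  equations: mono-exponential peak relaxation (the *flipping rate*),
  saturating dose dependence `Y = Y0 + (Plateau−Y0)(1−exp(−K·c))` with
  `K_on = (Plateau−Y0)·K` (the derivative at zero concentration),
  recovery `1−exp(−K_off·t)` for peak and steady-state protocols,
  four-parameter-logistic IC50 with unit Hill slope
  `Y = Bottom + (Top−Bottom)/(1+10^(X−logIC50))`, Michaelis–Menten
  `v = Vmax·X/(Km+X)`, and the competitive / non-competitive / mixed
  inhibition classification from Km and Vmax shifts.

Because atomistic trajectories and patch-clamp rigs are not shippable, the
package carries a first-class **synthetic world**: overdamped Langevin
dynamics of a latent occlusion coordinate on ligand-specific two-basin
potentials (outward-open vs occluded), emitted as noisy gate distances and
interaction energies; discrete Markov chains with known transition
matrices; and patch-clamp current traces with known flipping rate, K_on,
K_off and IC50. Every estimator in the package is validated against the
ground truth of this world.

## Worked example

```r
library(gatekin)

# six ligand conditions, 10 replicas each, full chain in one call
cfg <- run_config(seed = 1, outdir = "occlusion_run",
                  n_replicas = 6, n_steps = 12000, k = 100)
res <- run_pipeline(cfg)
sapply(res$results$msm$per_condition, function(x) round(x$occupancy, 3))
#>   5HT  P5HT  B5HT  M5HT   COC   apo
#> 0.897 0.525 0.282 0.137 0.076 0.140
```

The numbers are the stationary (MSM-derived) occupancy of the occluded
basin per ligand condition: serotonin occludes readily, the propyl
analogue sits near balance, the butyl analogue disfavours occlusion, and
the methyl analogue and cocaine essentially never occlude — the
conformational fingerprint separating transported substrates from
blockers. `occlusion_run/report.md` additionally tabulates the fitted
kinetic constants: for the serotonin condition this run prints a flipping
rate of 104.1 s⁻¹, K_on 6.63 µM⁻¹s⁻¹, K_off 0.567 s⁻¹ and IC50 4.38 µM —
single noisy-replicate fits recovered from synthetic traces generated at
104.30 s⁻¹, 6.3 µM⁻¹s⁻¹, 0.55 s⁻¹ and 4.49 µM.

Equivalent command line:

```sh
Rscript -e 'gatekin::gatekin_cli()' all --seed 1 --outdir occlusion_run
```

## Layout

| | |
|---|---|
| `R/simulate.R`, `R/potentials.R`, `R/patch_clamp.R` | synthetic world: Langevin occlusion dynamics, ligand profiles, discrete chains, current traces |
| `R/pdb.R`, `R/geometry.R`, `R/energy.R`, `R/occlusion.R` | featurization: PDB parsing, COM distances, Kabsch superposition, nonbonded energies, occlusion labels |
| `R/pca.R`, `R/fma.R` | collective modes: PCA, functional mode analysis, filtered RMSF |
| `R/tica.R`, `R/cluster.R`, `R/msm.R`, `R/surface.R` | tICA, k-means microstates, reversible MSMs, implied timescales, CK test, free-energy surfaces, bootstrap |
| `R/kinetics.R` | electrophysiology / uptake fits and inhibition classification |
| `R/pipeline.R` | configuration, orchestration, caching, reporting, CLI |

The methods vignette (`vignettes/occlusion-methods.Rmd`) documents the
model assumptions, parameter choices and known limitations.
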