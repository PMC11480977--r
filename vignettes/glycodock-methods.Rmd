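---
title: "Information-driven protein-glycan docking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-driven protein-glycan docking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(glycodock)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the parameters that matter,
and the places where the design was genuinely open and a choice had to
be made. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The docking model

`glycodock` treats protein-glycan complex prediction as an
information-driven pose search. The receptor is rigid throughout; the
glycan is rigid during the pose search and gains interface flexibility
only in the refinement stage. Three ingredients define the model:

1. **Ambiguous interaction restraints (AIRs)** encode binding-site
   knowledge. An *active* residue is restrained to lie at the
   interface: its restraint is satisfied if *any* member of the
   partner's target set is effectively close, through
   $d_{\mathrm{eff}} = (\sum_{ij} d_{ij}^{-6})^{-1/6}$ over all
   heavy-atom pairs between the anchor residue and the target
   residues. The $r^{-6}$ sum is the standard ambiguous-restraint
   aggregation: it is dominated by, and always bounded above by, the
   closest pair, so one good contact satisfies the restraint.
   *Passive* residues appear only as targets and are never penalized
   themselves. The restraint energy is a flat-bottom well — zero
   within the bounds, harmonic $kv^2$ for violations up to a switch
   point, then linear with matched value and slope — so restraint
   forces stay bounded at any violation.

2. **A multi-term score.** Models are ranked by
   $\mathrm{HS} = w_{vdW} E_{vdW} + w_{elec} E_{elec} + w_{desolv}
   E_{desolv} + w_{BSA} E_{BSA} + w_{air} E_{air}$, lower is better.
   $E_{vdW}$ and $E_{elec}$ are intermolecular 12-6 Lennard-Jones and
   Coulomb sums over heavy-atom pairs, Lorentz-Berthelot combined,
   with a cubic switch to zero over the last 1.5 Å before the 8.5 Å
   cutoff (smooth gradients for minimization). $E_{BSA}$ is the
   buried solvent-accessible surface area; $E_{desolv}$ is the
   empirical per-atom surface term
   $\sum \sigma_{solv}(\mathrm{SASA}_{free}-\mathrm{SASA}_{complex})$.

3. **Cluster-then-refine selection.** Rigid-body models are clustered
   on a pairwise RMSD matrix (average linkage), and the best few
   members of every cluster — not just the globally top-ranked
   models — are refined. This preserves pose diversity: a near-native
   cluster whose members rank modestly still sends representatives to
   refinement.

## Parameters, units, defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| interface cutoff | 3.9 | Å | heavy-atom contact definition for "true interface" residues |
| AIR upper bound | 2.0 | Å | conventional effective-distance bound for all-atom residues |
| AIR force constant | 50 | kcal/(mol Å²) | conventional restraint stiffness; not printed in the protocol literature, fully configurable |
| AIR switch violation | 1.0 | Å | harmonic-to-linear handover |
| AIR random discard | 0.5 | — | tolerance to false-positive interface information, redrawn per model |
| LJ/Coulomb cutoff | 8.5 | Å | pair cutoff with 1.5 Å cubic switch |
| relative permittivity | 10 | — | constant-dielectric screening |
| rigid weights (default) | 0.01, 1, 1, −0.01, 0.01 | — | historical rigid-stage weighting |
| rigid weights (vdW) | 1.0, 1, 1, −0.01, 0.01 | — | small-ligand weighting; the recommended setting for glycans |
| flexref weights | 1, 1, 1, 0, 0.1 | — | refinement-stage weighting |
| n models | 1000 (200/conformer) | — | rigid-body sampling depth |
| cluster cut | 2.5 | Å | average-linkage distance cut; min reported size 4 |
| flat cluster request | 50 (150 ensemble) | — | rigid-stage cluster-count cut before top-5 selection |
| SASA probe / points | 1.4 / 960 | Å / — | Shrake-Rupley water probe and sphere sampling |
| flexible zone | 5.0 | Å | receptor residues near the glycan that refinement may move |

The exact numeric weight vectors of the published scoring functions
are exposed in `scoring_weights()` and are deliberately configurable:
only the 0.01 → 1.0 van der Waals change between the two rigid-stage
presets is load-bearing for the method's headline behaviour, and both
presets are first-class.

Nonbonded parameters live in a compact editable table
(`nonbonded_params()`): one row per atom class (aliphatic/carbonyl/
sugar carbon, hydroxyl/carbonyl/sugar oxygen, N, S, plus an inflated
neutral "bulk" class used by the synthetic fixtures), with an
element-level fallback. A full force field cannot be carried inside a
self-contained package; the table is in the right range for organic
heavy atoms and every number can be overridden. Sugar carbons carry a
compensating positive charge so a heavy-atom-only monosaccharide is
net neutral — the hydroxyl protons that would balance it are not
represented.

## Search and refinement

**Rigid stage.** Starting poses draw a uniform rotation (normalized
4-normal quaternion) and place the glycan centroid at a random
direction at bounding-sphere separation plus 3 Å, guaranteeing a
clash-free start. Each pose is minimized over the six rigid degrees
of freedom by Nelder-Mead direct search (two coarse rounds plus one
fine round, 300 iterations each by default) on
$E_{air} + w_{vdW}E_{vdW} + w_{elec}E_{elec}$. Two deliberate choices
here:

* *Restraint forces drive the search at full strength* regardless of
  the small $w_{air}$ used for ranking. The restraint term's job
  during minimization is to steer the ligand into the encoded
  interface; its job in the score is to de-prioritize models that
  ended up elsewhere. Conflating the two weights makes the funnel too
  weak to beat incidental surface minima.
* *Surface terms are excluded from the search objective* (they are
  comparatively expensive and noisy per step) and computed once for
  the final score.

Direct search instead of analytic gradients is a robustness choice at
this scale: the 6-dimensional objective is cheap, and the switched
potentials plus the $d_{\mathrm{eff}}$ kink at the flat-bottom edge
make gradient bookkeeping error-prone for little gain.

**Refinement stage.** Full torsion-angle simulated annealing is
replaced by a two-stage restrained Cartesian minimization with the
same flexibility schedule: stage 1 moves interface side chains and
the whole glycan, stage 2 additionally the interface backbone. The
objective adds stiff harmonic restraints on covalent bond lengths
(k = 300 kcal/(mol Å²)) and 1-3 distances (k = 60, an angle
surrogate) to the pairwise score terms, with analytic gradients and a
greedy adaptive-step descent (500 evaluations per stage by default).
This is loudly an approximation of the annealing protocol: it
reproduces the qualitative effect — clash relief and local pose
improvement with preserved covalent geometry — without molecular
dynamics. Geometry is guarded twice: torn input geometry is rejected
up front, and any bond stretching beyond 0.5 Å during refinement
rejects the result and returns the input model flagged.

**Conformer presampling** perturbs every glycosidic linkage's two
torsions by Gaussian deviates (σ = 20°·√effort) with rings rigid,
resolves residual clashes by a short repulsive relaxation, and
reduces the ensemble to cluster centers (20 by default; each center
minimizes mean RMSD to its co-members). The `effort` multiplier
stands in for running a longer sampling schedule; `effort = 16` with
400 models mirrors the heavier preset. Centers rarely coincide with
the lowest-RMSD member sampled, so reduction loses a little fidelity
by construction — the tests assert exactly this one-sided loss.

## Numerical choices

* Pairwise RMSD matrices superpose each model pair on the same
  selection used for measurement (scenario-dependent: both interfaces
  for ti-aa, protein interface plus whole glycan for tip-ap). After
  rigid docking all models share the receptor frame, so a
  superposition-free mode exists (`superpose = FALSE`), but pairwise
  fitting is the default since refined models no longer share a frame.
* Superposition uses the SVD formulation with the determinant
  correction (proper rotations only); collinear selections are
  rejected as degenerate rather than silently fitted.
* Hierarchical clustering delegates to `stats::hclust/cutree`
  (average linkage); the test suite proves equivalence against an
  exhaustive agglomeration oracle for every random matrix up to
  n = 8. Cutting to N flat clusters happens *before* the minimum-size
  filter, so fewer than N clusters may be reported; dropped members
  stay available in an unclustered pool.
* Ties everywhere break by (score, model id); cluster rank ties by
  smallest leading model id. Tables are written with fixed `%.6f`
  formatting so identical runs are byte-identical.
* All randomness flows through per-model seeds derived from the run
  seed by integer hashing below 2³¹; drawing a model's restraint
  subset or pose never perturbs the caller's RNG stream.
* IL-RMSD boundary values map to the stricter tier (cutoffs are
  inclusive: 1.0 Å is high).

## The synthetic study system

`make_toy_complex()` builds the test bed: an idealized glycan of 2-7
hexagonal pseudo-pyranoses (ring C₅O plus exocyclic oxygens; the
anomeric C1-O4 linkage geometry is respected, successive units twist
by an incommensurate 100° so the chain has no screw symmetry, and the
reducing-end unit carries an acetamido-like arm as on
N-acetylglucosamine) cradled by an engineered receptor pocket: one
pseudo amino-acid per glycan surface atom, presenting a
charge-complementary partner atom at near-optimal van der Waals
contact with its spin optimized against the bound glycan, backed by a
grid of coarse neutral bulk atoms so the site is reachable only from
its open face. The constructed complex is then rigidly relaxed under
the package's own energy model, and the relaxed pose is the reference
"bound" pose — exactly as one would energy-minimize an experimental
complex before using it as a docking reference. True-interface AIRs
derived from a reference are calibrated so the reference pose
satisfies them (`calibrate_bounds = TRUE`): the conventional 2.0 Å
bound presumes all-atom residues, and a restraint violated by the
truth it encodes would bias the search away from it.

What the fixtures *do* emulate: interface detection geometry,
ambiguous-restraint mechanics, funnel-shaped energetics with decoy
minima (the flipped and slid poses are real competing basins),
clash-relief refinement, clustering structure, and every bookkeeping
contract. What they do *not* emulate: real carbohydrate
stereochemistry and ring puckering, protonation, water-mediated
contacts, receptor conformational change, and force-field accuracy.
A passing suite therefore demonstrates that the machinery is correct
and that the method behaves as designed on a well-posed instance — not
that any particular success rate transfers to experimental
benchmarks, which require external structures and cluster-scale
sampling.

Problem sizes used by the tests and the acceptance script — 200
rigid-body models per scenario on a 3-unit toy, 600 for the ensemble
bookkeeping run at reduced minimizer iterations, 40-member conformer
ensembles — are chosen as the smallest sizes at which the assertions
are meaningful and stable across seeds.

## Known limitations

* The refinement is a minimizer, not an annealer: it cannot cross
  barriers, so it fixes clashes and tightens contacts but will not
  repack a wrongly threaded glycan.
* Scoring carries no CH-π stacking term, a known gap for
  carbohydrate-aromatic interactions.
* The monosaccharide catalogue is a name list, not a chemical
  perception engine; unusual residue codes must be added via
  `options(glycodock.monosaccharides = ...)`.
* Single receptor + single glycan only; no multi-body docking, no
  covalently linked (glycosylation-site) glycans, no mmCIF input.
* `branched = TRUE` toys need at least 4 units: a degree-3 linkage
  vertex does not exist in a smaller tree, so 2-3 unit "branched"
  chains are topologically linear under the path definition used for
  the size classes.
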