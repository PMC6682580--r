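---
title: "Quantifying the pose-consistency of 3D molecular descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the pose-consistency of 3D molecular descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structure-based virtual screening pipelines dock each candidate ligand into a
receptor and keep several scored poses per compound. When those poses are then
converted into 3D molecular descriptors — for machine-learning models or QSAR
work — every pose of the same compound yields a different descriptor vector.
If that spread is large relative to the spread between compounds, the
descriptor representation is effectively noisy, and model quality suffers in
ways that are invisible if only one pose per compound is ever inspected.

`posestab` measures this effect. For each compound it takes the ensemble of
docking poses (at most ten, the usual cap in Glide-style workflows), computes
a full 3D-descriptor vector per pose, and summarises:

* **descriptor variability** — the standard deviation of each descriptor
  across the compound's top-*k* poses (by docking score), averaged over
  descriptors after z-standardization;
* **atom-position variability** — the mean root-mean-square fluctuation
  (RMSF) of heavy-atom positions after Kabsch superposition of the same
  poses;

and then asks the population-level questions: do active and inactive
compounds differ in pose consistency, how strongly does consistency degrade
with conformational flexibility (rotatable bonds), and which individual
descriptors are intrinsically stable or unstable.

## The descriptor inventory

Five families are computed per conformer (238 values in this implementation;
the exact inventory of 3D-descriptor suites is toolkit- and
version-dependent, so the count is documented rather than promised):

* **3D-MoRSE** (192): weighted pair sums
  $\mathrm{Mor}_w(s) = \sum_{i<j} w_i w_j \,\frac{\sin(s\,r_{ij})}{s\,r_{ij}}$
  for scattering parameters $s = 0,\dots,31\ \text{Å}^{-1}$ (index
  $s_\text{index} = s + 1$) and six weighting schemes: unweighted, mass,
  van der Waals volume, Sanderson electronegativity, polarizability (all
  carbon-normalised) and signed partial charge. The index convention is
  pinned by an observable: at the first index the kernel is identically 1,
  so the descriptor collapses to a composition constant with *zero* variance
  across poses — which is exactly how the first MoRSE descriptor behaves in
  practice, and a useful internal control for any pipeline of this kind.
* **CPSA** (30): the Stanton–Jurs charged-partial-surface-area set, combining
  per-atom Shrake–Rupley solvent-accessible areas with Gasteiger–Marsili
  partial charges (PPSA/PNSA 1–3, DPSA, fractional and surface-weighted
  forms, relative charge/surface terms, and the |q| < 0.2 atomic/charged
  split).
* **Gravitational indexes** (6): $\sum m_i m_j / r_{ij}^2$ over all and over
  bonded pairs, plus square and cube roots.
* **Moments of inertia** (6): sorted eigenvalues of the inertia tensor about
  the centre of mass and their three ratios.
* **Geometric indexes** (4): per-atom eccentricities of the geometric
  distance matrix, their min/max (radius $R$, diameter $D$), the 3D
  Petitjean index $(D-R)/R$ and a selectable "shape index" variant (the
  same $(D-R)/R$ by default, $D/R$ as the alternative — published
  definitions of the geometric shape index genuinely differ, so the choice
  is an exposed parameter rather than a hidden convention).

Undefined values (charge weighting with no charges, ratios with vanishing
denominators, CPSA halves with no charged atoms) are flagged `NA` and
excluded from downstream averages; silently imputing zeros would bias every
variability statistic.

### Surface and charge models

The solvent-accessible surface uses uniform sphere sampling with a
deterministic Fibonacci-spiral point set (default 960 points, probe radius
1.4 Å, both configurable; probe 0 gives the bare van der Waals surface). The
point set is oriented along the molecule's principal axes with signs fixed by
third coordinate moments, so the sampled surface rotates rigidly with the
molecule and all SASA-derived descriptors are rigid-motion invariant to
machine precision for generic geometries; for exactly symmetric molecules the
residual frame ambiguity is itself a molecular symmetry and changes areas
only at sampling accuracy. At 960 points the area of an isolated sphere is
within 2% of the analytic value, and cluster areas move by under 1% when the
density is quadrupled.

Partial charges default to PEOE (Gasteiger–Marsili) with the classic
parameter set for H, C, N, O, S, P and halogens and $(1/2)^n$ damping over 8
iterations — ample for convergence well below $10^{-3}$ e. Charges read from
input SD tags take precedence, so pipelines whose charges came from the
docking program reproduce exactly. Atom hybridisation classes are inferred
from bond orders.

### Hydrogens

Descriptors use every atom present in the input (matching the common
descriptor-toolkit default of keeping explicit atoms); superposition and the
atom-variability statistic use heavy atoms only, because docking programs
place hydrogens erratically. This asymmetry is deliberate and worth knowing
about: adding or removing explicit hydrogens changes descriptor values.

## The consistency statistics

**Standardization before averaging.** Raw descriptor scales span many orders
of magnitude (a gravitational index in the hundreds, a Petitjean index below
one), so the "average std over all descriptors" is only meaningful after
per-descriptor z-scaling over all (compound, pose) rows entering the
analysis. The model records and drops constants (sd < 1e-12) and
majority-undefined columns. The scaling is fitted per ensemble depth *k* on
the top-*k* rows, keeping each depth's analysis self-contained; a raw-scale
mode remains available (`standardize = FALSE`) and is the right scale for
*between-dataset* comparisons, where renormalisation would mask real
differences — the generator's own noise-monotonicity check uses it.

**Std divisor.** Population form (divisor *n*) by default, sample form
(*n − 1*) switchable. Group comparisons are divisor-invariant, so the choice
is cosmetic for the headline results; it is exposed because per-compound
absolute numbers do depend on it.

**Top-k selection.** Poses are ranked by docking score ascending (Glide
convention: lower is better) with ties kept in file order; the reference
pose for superposition is the best-scoring one, which makes every statistic
deterministic. Compounds left with fewer than two poses are skipped and
reported in a sidecar table, never silently dropped. The workflow's standard
depths are k = 3, 5 and 10.

**Superposition.** Pairwise Kabsch alignment of every selected pose onto the
reference (SVD with reflection correction), heavy atoms only. Iterative
alignment to the evolving mean structure is a documented possible extension;
for ensembles of ≤ 10 poses the difference is well below the effects being
measured. RMSF is the 3D positional deviation about the mean aligned
position (not per-axis stds averaged), with the same divisor convention as
above. One caution discovered while validating: RMSF about the *mean* is not
monotone under duplicating the reference pose — a duplicated pose only
shrinks an atom's variance if it lies within about one standard deviation of
that atom's mean position — so no such monotonicity is claimed or tested;
duplicating an entire ensemble, by contrast, provably leaves the population
RMSF unchanged and is the invariant the tests pin.

**Group comparison and correlation.** Activity labels follow strict
thresholds on the effective Ki (below 100 nM active, above 1000 nM inactive,
boundaries and everything between ambiguous; Ki = IC50/2 when only IC50 is
known, Ki wins when both are present). Ambiguous and unlabeled compounds are
excluded from the class comparison but retained in the flexibility
correlation, which is not an activity question. The correlation is plain
Pearson between rotatable-bond count and mean descriptor std, per depth; an
empty class yields missing cells, never zeros.

**Rotatable bonds** are counted as acyclic single bonds between two
non-terminal heavy atoms (each end bonded to at least one further heavy
atom). There is no universal definition; this one is the common core of the
major toolkits, and an optional amide-C–N exclusion flag eases cross-checks
against toolkits that apply it. Ring membership comes from bridge detection
on the bond graph.

## The synthetic benchmark

Real inputs for this kind of study — ChEMBL actives/inactives docked with a
commercial engine into GPCR crystal structures — cannot ship with a package.
The generator replaces them with ensembles that have the same *statistical
anatomy*, so every pipeline property remains testable:

* compounds are branched heavy-atom chains (ideal 1.5 Å bonds, tetrahedral
  angles, C/N/O decoration so every weighting scheme is non-trivial) with an
  exact, controlled rotatable-bond count spanning 1–10 uniformly;
* each of up to ten poses perturbs every rotatable torsion by
  $N(0, \sigma_t^2)$, adds isotropic coordinate jitter, then a random rigid
  motion; docking scores equal a base value plus the torsional perturbation
  magnitude plus noise, so better scores mean geometries closer to the base
  conformer and top-k selection is meaningful;
* the two activity classes alternate (phase-shifted against the
  rotatable-bond cycle so class and flexibility stay unconfounded) and
  differ only in torsional noise; affinities are drawn log-uniformly inside
  each class's own range so labels round-trip through the thresholds, with a
  10% ambiguous slice and a third of compounds reporting IC50 instead of Ki
  to exercise both labeling paths;
* every compound derives its RNG stream from (master seed, compound index),
  so datasets are reproducible and stable under changes of `n_compounds`,
  and a flat-text manifest replays the exact dataset byte-for-byte.

Defaults are chosen once as the package's reference conditions: torsional
noise 0.35 rad (active) vs 0.20 rad (inactive) — the class asymmetry
mirrors the 5-HT~1B~-like pattern where actives superpose *worse* than
inactives — jitter 0.15 Å, score noise 0.5. Under these conditions heavy-atom
RMSF values fall in the 0.2–0.5 Å range, the same order as real docking
ensembles, and the flexibility effect is strong enough that the pipeline
recovers r > 0.3 at k = 10 comfortably.

What the generator does **not** emulate: force-field energetics, steric
clash resolution, receptor shape (poses are unconstrained by any pocket),
protonation/tautomer enumeration, or any particular scoring function.
Passing tests on this benchmark therefore demonstrate that the *pipeline*
recovers planted statistical structure — not that any particular receptor
dataset will show a given effect size.

## Embedding and export

Per-compound vectors of per-descriptor stds (dimension = retained
descriptors) are projected to 2D for visual inspection. The defaults are
deliberately deterministic — PCA or classical metric MDS, which coincide up
to isometry on Euclidean data — rather than a stochastic neighbour embedding:
for a test-covered, reproducible package, bit-stable coordinates outweigh
fidelity to any particular visualisation tool, and the embedding method is a
plug-in point (any function of the same vectors can be swapped in). The
export table carries coordinates, activity label, the red/black
active/inactive colour convention, both consistency scores and optional
structure strings, as CSV or JSON-lines.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 96–192 sphere points for
surface areas inside large benchmark loops (convergence is ~1% at 960;
the statistics compared are unaffected at these resolutions, as they are
means over hundreds of descriptors), the full 960 points wherever a single
area is checked against its analytic value; benchmarks of 200 compounds ×
10 poses × 3 seeds for the planted-effect recovery; and 100 random cases for
the isometry suite at tolerance 1e-8 relative. Degenerate inputs are
handled explicitly: coincident atoms error in the gravitational index and
flag the geometric indexes, near-zero inertia denominators flag the ratios,
collinear or undersized atom masks error in Kabsch, and sub-2-pose
ensembles are skipped with a reason.

## Known limitations

* The descriptor inventory approximates the classic five-family 3D set but
  is not a drop-in reproduction of any specific toolkit version; CPSA
  surface/charge conventions in particular vary between implementations.
* Gasteiger parameters cover organic chemistry (H, C, N, O, S, P, halogens);
  anything else must arrive with precomputed charges.
* Pose ensembles must share atom order; there is no graph matching across
  tautomers or protomers.
* The canonical surface frame can differ by a reflection between poses of
  exactly symmetric molecules (where it is harmless by symmetry); molecules
  *near* such symmetry can in principle see sampling-level (≪1%) SASA
  discrepancies between poses.
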