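---
title: "Quantifying binding-partner-dependent loop conformations from trajectory ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying binding-partner-dependent loop conformations from trajectory ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopstates)
```

## The problem

Flexible surface loops of receptor proteins often populate several distinct
conformations, and a binding partner can change how much time the loop
spends in each — either by selecting a pre-existing conformation or by
remodelling the loop into a new one. The immune checkpoint receptor PD-1 is
the motivating case: the loop connecting its B and C β-strands adopts
different conformations depending on whether the receptor is unbound, bound
to its natural ligand, or bound to a blocking antibody. Deciding between
those scenarios requires turning raw trajectory ensembles (one per binding
state) into a small set of interpretable numbers: per-atom flexibilities,
conformational clusters with per-system occupancies, a low-dimensional map
of how those clusters relate, and interface interaction summaries.

`loopstates` implements that analysis chain end to end:

1. **Superposition** — least-squares (Kabsch) rigid-body fits;
2. **Descriptors** — RMSF and fitted RMSD;
3. **Clustering** — greedy neighbour-count (Daura/GROMOS) RMSD clustering;
4. **Ordination** — non-metric MDS of cluster-centre distances with
   single-linkage meta-cluster grouping and occupancy accounting;
5. **Interactions** — geometric hydrogen-bond detection and short-range
   Coulomb/Lennard-Jones energy sums;
6. **Synthetic data** — a generator of multi-system ensembles with planted
   conformational states, so the whole chain is testable without access to
   any particular simulation data set.

## Models and procedures

### Superposition and descriptors

All fits are unweighted least squares over a *fit selection* (typically the
Cα atoms of the regions flanking the loop), solved by SVD of the 3×3
covariance with the determinant-sign correction, so only proper rotations
are returned. Degenerate (collinear) fit selections are refused rather than
silently resolved.

The per-atom fluctuation is

$$\mathrm{RMSF}(\mathbf{x}) = \sqrt{\tfrac{1}{T} \sum_{t=1}^{T}
  \lVert \mathbf{x}(t) - \bar{\mathbf{x}} \rVert^2},$$

the standard deviation of an atom's position about its time average after
each frame has been superposed on a common reference. Two reference
conventions circulate: fitting every frame to the *first* frame, and
fitting to the *mean* structure. They differ when the mean drifts, so both
are exposed (`reference = "first"` is the default, `"mean"` iterates the
fit/mean cycle to stability); neither is silently chosen for the user.

The deviation of a frame from a reference over a *measure selection* of
$N$ atoms is

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{N} \sum_{i=1}^{N}
  \lVert \mathbf{x}_i - \mathbf{x}_i^{\mathrm{ref}} \rVert^2},$$

evaluated after the fit over the (generally different) fit selection. The
loop analysis uses exactly this split: fit on flanking Cα, measure over all
loop atoms. No mass weighting is applied anywhere — the formulas above are
the unweighted ones, and fits are on Cα only.

### Neighbour-count clustering

The conformational clustering is the greedy rule of the GROMOS tradition:
every structure is a candidate centre; the structure with the most
neighbours within the RMSD cut-off (the count includes the candidate
itself) becomes a cluster centre; the cluster is removed; repeat. Ties in
neighbour count are broken by the lowest frame index, and clusters are
numbered by descending size, so results are bitwise deterministic. The
member count of a cluster divided by a system's frame total is the fraction
of time that system's loop resided in that conformation; composition
denominators are per-system, so "82% of the apo frames fall in cluster 2"
style statements read directly off the output.

The default cut-off is **0.2 nm**: small enough to separate conformations,
large enough not to over-differentiate thermal noise. `cutoff_sweep()`
exposes the trade-off, and `incremental_cluster_count()` reports the
cluster count over growing trajectory prefixes as a sampling-convergence
diagnostic. That count usually grows and levels off, but the greedy
algorithm gives no monotonicity guarantee, so the package reports the curve
and asserts nothing about its shape.

### Non-metric MDS and meta-clusters

Cluster-centre RMSD matrices are embedded in 2D by non-metric MDS
minimizing Kruskal's stress-1,

$$S = \sqrt{\frac{\sum_{i<j} (d_{ij} - \hat d_{ij})^2}
                 {\sum_{i<j} d_{ij}^2}},$$

where $\hat d$ are disparities from monotone (isotonic) regression of the
embedded distances on the input dissimilarity order. Each iteration first
proposes a Guttman (majorization) update and accepts it only if stress-1
drops, otherwise it falls back to a steepest-descent step with a
back-tracking line search — so the reported stress trace is non-increasing
by construction. Iteration stops when the per-step improvement falls below
`tol` (default 1e-6) or after `max_iter` (default 500) steps.

Two numerical choices deserve explanation:

* **Ties share a disparity.** Tied dissimilarities are pooled to one
  disparity value (weighted pool-adjacent-violators). Under a
  strictly-primary tie treatment any triangle achieves zero stress for
  three equal distances, so exactly embeddable configurations with repeated
  distances would be recovered only up to rank order; with pooled ties they
  are recovered up to a similarity transform.
* **A classical-scaling start anchors distance ratios.** Small centre sets
  (four or five points) admit whole families of rank-preserving embeddings
  with very different distance ratios, all at zero stress; which one a
  random start reaches is arbitrary, which would make any fixed grouping
  threshold fragile. The optimizer therefore runs one deterministic
  classical (Torgerson) start plus `n_restarts` (default 4) seeded random
  restarts and keeps the lowest stress, with the classical start winning
  ties. Everything is reproducible bit for bit from the seed, and the final
  configuration is canonically oriented (centred, principal axes, fixed
  signs) and scaled back to the input dissimilarity scale.

The published style of analysis circles groups of clusters in the
ordination plot by hand. `group_metaclusters()` replaces that manual step
with a deterministic rule — single-linkage connected components of the
embedded points at a user-set threshold — trading fidelity to a by-eye step
for reproducibility; the threshold is recorded in every output. Only the
top K clusters (default 25) are embedded; frames in later clusters are
reported in an explicit `"unassigned"` remainder rather than silently
dropped, so per-system occupancies always sum to one.

For intuition on instance variability: embedding 10 points drawn from a 5D
Gaussian into 2D gives Spearman rank agreement between input and embedded
distances anywhere from about 0.83 to 0.96 depending on the draw — that
spread is a property of the dimensionality reduction, not of the optimizer
(an independent implementation reaches the same stress to within a few
thousandths on the same inputs).

### Hydrogen bonds and short-range energies

A donor/hydrogen pair and an acceptor in opposite groups form a hydrogen
bond when the donor–acceptor distance is at most **0.35 nm** and the
hydrogen lies within **30°** of the donor→acceptor axis (the
acceptor–donor–hydrogen angle at the donor). That vertex convention is
deliberate: a 30° cut-off on the angle *at the hydrogen* would describe a
folded, non-bonding geometry. The near-linear alternative
(donor–hydrogen–acceptor ≥ 150°) is available via
`angle_convention = "DHA"`. Donor–hydrogen covalency comes from the
topology's bond table; –OH/–NH groups are donors and –O/–N acceptors in
the bundled topologies.

Interaction energies between two disjoint groups are plain short-range
pair sums within a **1.4 nm** cut-off:

$$E_{\mathrm{Coul}} = f \sum_{i,j} \frac{q_i q_j}{r_{ij}}, \qquad
  E_{\mathrm{LJ}} = \sum_{i,j} \frac{C_{12,ij}}{r_{ij}^{12}} -
  \frac{C_{6,ij}}{r_{ij}^{6}},$$

with $f = 138.935458$ kJ mol⁻¹ nm e⁻² and geometric-mean combination
$C_{6,ij} = \sqrt{C_{6,i} C_{6,j}}$ (likewise $C_{12}$), the combination
rule of the force-field family the bundled parameters mimic. No switching
function, no long-range correction, no periodic images: the quantity is
the truncated short-range sum, which is what interface histograms
summarize. Histograms use half-open bins $[k w, (k+1) w)$ anchored at zero
(edge values go to the higher bin); typical widths are 100 kJ/mol for a
whole interface and 10 kJ/mol for a loop–ligand contact.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cluster_cutoff` | 0.2 | nm | neighbour cut-off of the greedy clustering |
| `hbond_dist` | 0.35 | nm | donor–acceptor distance cut-off |
| `hbond_angle` | 30 | degrees | angular cut-off (at the donor) |
| `energy_cutoff` | 1.4 | nm | short-range pair-sum truncation |
| `ebin_wide`, `ebin_narrow` | 100, 10 | kJ/mol | energy histogram bin widths |
| `top_k` | 25 | — | clusters carried into the ordination |
| `meta_threshold` | 0.8 | input scale (nm for RMSD inputs) | single-linkage grouping threshold |
| `mds_tol`, `mds_max_iter`, `mds_restarts` | 1e-6, 500, 4 | — | ordination controls |
| `noise_sigma` | 0.02 | nm | generator thermal noise per coordinate |

The loop and flanking selections are deliberately *required* configuration
(`loop_query`, `flank_query`): residue numbers delimiting a flexible loop
are a property of the protein under study, not of the method, and guessing
them silently would be worse than asking.

## What the synthetic generator emulates — and what it does not

`generate_loop_ensemble()` produces frames in which a designated loop
switches among K planted conformations while flanking scaffold atoms stay
put up to Gaussian noise, optionally under a random global rigid motion per
frame (which exercises the superposition stage; all fitted quantities are
invariant to it). State templates are a loop arc rotated about the hinge
axis through its anchors by per-state angles — a single-dihedral
deformation giving direct control over inter-state RMSD. Switching is
i.i.d. by default or first-order Markov, which gives prefixes a time
structure (late-appearing states) for the convergence diagnostic.

The default three-system plan encodes the occupancy structure of a receptor
whose loop is remodelled differently by two partners: four states S1–S4 at
hinge angles 0°/45°/135°/225°, giving loop RMSDs of about 0.58 nm between
S1 and S2 and 1.05–1.52 nm between all other pairs, mixed as

* apo = 0.8 S3 + 0.2 S1,
* ligA = 0.25 S1 + 0.45 S2 + 0.30 S4,
* ligB = 0.60 S1 + 0.40 S2.

Under the default cut-off and threshold this yields three
meta-conformations — one shared (S1+S2), one apo-exclusive (S3), one
ligA-exclusive (S4) — with residencies 80/20 (apo), 70/30 (ligA) and 100%
(ligB), and a core conformation shared 20/25/60% of the time. The
generator's defaults sit firmly in the well-separated regime: intra-state
frame-pair RMSD is about $\sigma\sqrt{6} \approx 0.05$ nm, a quarter of
the cluster cut-off, while inter-state RMSDs exceed it several-fold.

What the generator does **not** emulate: physically realistic dynamics
(no force field, no inertia, no solvent), gradual conformational
transitions (switches are instantaneous), anharmonic or correlated
intra-state fluctuations (noise is isotropic and independent per atom),
and energetics consistent with the geometry (interaction fixtures are
separate, purpose-built dimers). Passing tests on generated data therefore
demonstrate the correctness of the *analysis chain* — recovery of planted
occupancies, exact oracle agreement, determinism — not the realism of any
simulation.

## Numerical and degenerate-input policy

* Kabsch fits require ≥3 non-collinear fit atoms; reflections are excluded
  by the determinant correction; SVD ordering fixes sign conventions.
* Single-frame RMSF is refused (zero variance would be reported as silent
  zeros otherwise).
* RMSD matrices are symmetrized after computation (the two directions agree
  analytically; symmetrization removes rounding asymmetry) with a hard zero
  diagonal.
* Distance matrices with asymmetry, negative entries, or a non-zero
  diagonal are rejected, as are non-positive cut-offs and thresholds.
* All-zero dissimilarity matrices and sets of fewer than three centres are
  refused by the ordination.
* Coincident atoms across energy groups (r = 0) are an error, not an
  infinity.
* Empty selections are always an error, never a silent empty result.

## Problem sizes

The shipped analysis scripts run three systems of 800 frames each; the
test suite exercises the chain up to a 10,000-frame single-system ensemble
and a 4,500-frame three-system ensemble (the pairwise RMSD kernel is
compiled, so the 10,000-frame matrix — 5×10⁷ fitted pairs — takes on the
order of two minutes on one core); the acceptance script uses 2,000 frames
per system. These sizes were chosen so binomial sampling error on recovered
occupancies (about ±1% at n = 2,000, ±3σ) sits well inside the planted
effect sizes.

## Known limitations

* No periodic-boundary handling: all distances are plain Euclidean. All
  analyzed quantities are intra-/inter-protein at ≤1.4 nm and the synthetic
  ensembles are generated whole, so no image ever matters here, but
  trajectories wrapped across a box must be made whole before import.
* PDB is the only trajectory interchange format (text, multi-model);
  binary trajectory formats would need external conversion.
* The ordination embeds in 2D only, and meta-cluster grouping has exactly
  one knob (the linkage threshold); no automatic threshold or
  meta-cluster-count selection is attempted.
* Energies are bare truncated sums — no PME/reaction-field electrostatics,
  no dispersion correction — and are therefore comparable between groups
  and frames, not to ensemble-average observables.
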