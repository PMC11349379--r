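---
title: "Methods: cross-link validation, burial differentials and rigid-body fitting in xlinkfit"
author: "xlinkfit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-link validation, burial differentials and rigid-body fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`xlinkfit` implements the computational core used to validate and build
models of polymeric protein assemblies that exist in two conformational
states — the motivating system being intraflagellar-transport (IFT) trains,
which run along ciliary microtubules as a compact stacked polymer in one
direction and re-polymerise into an extended 2-fold-symmetric polymer for
the return trip. Three questions drive the design:

1. Do in-situ cross-linking mass-spectrometry (XL-MS) residue pairs agree
   with a multi-copy assembly model, and do they discriminate between the
   two conformational states?
2. Which residues are surface-accessible in one state but buried in the
   other, i.e. candidate state-specific interaction sites?
3. Can rigid subcomplex models be placed into a low-resolution density map
   by global optimisation under the restraint weights and annealing regime
   used for the trains?

Everything is exercisable on synthetic two-state assemblies with planted
ground truth, so the whole pipeline is testable without downloading any
deposited data.

# Cross-link validation

## Distance mapping with copy ambiguity

A residue-level cross-link names two (protein, residue) endpoints, not two
chains. In a polymer every protein exists in many copies, so the package
maps each endpoint to *all* Cα sites of that protein/residue (author
numbering; `label_seq_id` is ignored because residue labels in cross-link
identifications are author/UniProt-style) and takes the **minimum Cα–Cα distance over all copy
pairs**. This is the most permissive structurally consistent assignment:
a link is violated only if *no* pair of copies could explain it. When both
endpoints are the same protein and residue, pairing a site with itself is
excluded, so such links are measured between two different copies.

The only distance used is Cα–Cα. No linker geometry or side-chain
modelling is attempted; the conventional bound for a DSSO-linked lysine
pair already refers to Cα atoms.

## Classification and rescue

* **Threshold**: 35 Å by default, *strict* — satisfied iff `d < 35`.
  A distance of exactly 35.0 Å is a violation. The strictness follows the
  "< 35 Å" convention; ties are vanishingly rare on real coordinates but
  the rule must still be deterministic.
* **Unmapped** links (endpoint protein absent from the chain map, or the
  residue not modelled) are a third class, excluded from histograms and
  satisfaction fractions and reported separately. They are never errors.
* **Flexibility rescue**: a violated link is rescued when an endpoint
  residue has per-residue confidence (pLDDT, carried in the B-factor
  column, mean over the residue's atoms) below 50. The rescue window
  (residues scanned up/downstream on the same chain) defaults to 0 —
  endpoint only — because the underlying rule is stated per flexible
  region without a numeric window; the window is exposed as a parameter
  for users who want to treat whole loops as flexible.

Ambiguous-site links (e.g. alternative N-terminal lysines) are reported as
separate rows, one per alternative, rather than collapsed to a single
minimum: the reporting stays faithful to the input identifications, and a
user can collapse rows afterwards if desired.

## Two-state comparison

`compareStates()` maps the same record set onto both conformations (each
with its own chain map) and reports `dA`, `dB`, both classifications and
`delta = dB − dA`. The companion histogram uses fixed-width bins over
`[0, max)`, left-closed, so the bin counts always sum to the number of
mapped links.

# Surface burial differential

Solvent-accessible surface area is computed with a Shrake–Rupley sphere
sampling: 960 deterministic golden-spiral points per atom, probe 1.4 Å
(water). Determinism matters more here than marginal accuracy — the same
model must give the same answer on every run — and doubling the point
count changes per-residue areas by well under 3% of the reference area on
the package's fixtures.

Relative accessibility divides residue SASA by a reference maximum:
Tien-style theoretical maxima for full-atom residues, and the isolated
bead sphere area `4π(r+1.4)²` for coarse-grained single-bead residues
(bead radius 3 Å, roughly a residue-sized sphere). A residue counts as

* **accessible** at relative accessibility ≥ 0.25,
* **buried** below 0.10.

Both cutoffs are configuration keys: the source analysis publishes no
numeric values, so defaults follow common practice for
accessible/buried calls. The *differential* is then defined per residue
matched across states by (protein, copy, author number): accessible in one
state *and* buried in the other. The two sets are disjoint by construction
and swap exactly under state exchange — that antisymmetry is asserted in
the tests rather than assumed.

Burial is computed in whatever assembly context the model provides; the
package does not generate symmetry mates. Patches are formed by
single-linkage clustering (connected components of the inter-residue
minimum-heavy-atom-distance graph at a 6 Å default cutoff), numbered by
decreasing size.

## Polymer geometry metrics

The polymer axis is the first principal component of the Cα coordinates —
depositions carry no axis annotation, and for a train-like assembly PC1 is
unambiguous. `trainMetrics()` reports IFTB:IFTA complex stoichiometry from
the chain map's subcomplex labels, the axial extent, and the spacing
between consecutive repeating-unit centroids along the axis. The ratio of
extended-state to compact-state train length is deliberately *not* reduced
to a single headline percentage: such a ratio depends on conventions that
are not standardised (which polymer sets the compact length, and whether
the visible repeat spans one or two symmetry-related units), so the
package exposes the raw geometry and leaves the ratio to
the user. Relatedly, units-per-visible-repeat is a generator parameter
(default 2, matching the 2-fold symmetric interpretation), not a
hard-coded assumption.

# Rigid-body fitting

## Density simulation and the EM term

Model density is a sum of per-atom Gaussians with
`σ = resolution / (2√(2 ln 2))` (resolution = FWHM), truncated at 3.5σ,
sampled on a cubic grid. The EM agreement of a configuration is
`1 − mean(CC)` over bodies, where CC is the Pearson correlation between
the posed body's simulated density and the target map over the body's own
support. Zero-variance overlap (flat map, or a body outside the grid) is
defined as CC = 0.

## Score

The configuration score is a weighted sum with the weights used for
integrative train fitting —
connectivity 1, cross-link 30, discrete 10000, excluded volume 10,
EM 1000. Only the restraint names and weights are fixed; the functional
forms are a package choice — the simplest ones consistent with the
restraint names — and are kept switchable:

* cross-link: flat-bottom quadratic `max(0, d − 35)²` on the minimum
  Cα–Cα distance over copies;
* connectivity: `max(0, gap − maxGap)²` per declared chain continuation;
* excluded volume: count of inter-body atom sphere overlaps;
* discrete: 0/1 per declared required contact;
* EM: `1 − mean CC` as above.

The total is validated to equal the weighted term sum to 1e-9, and — with
the EM term switched off — is invariant under a global rigid motion of all
bodies together (asserted in tests).

## Fit libraries

Rotations are sampled quasi-uniformly over SO(3) by Shoemake's mapping of
a Halton sequence — deterministic, so a library is a pure function of its
inputs. Translations come from a Halton sequence over the grid box,
restricted to a sphere (radius default 200 Å) around the map centre and to
points whose voxel lies on map support: a pose whose centroid is in empty
space cannot pass the inside filter, so those are pruned before scoring.
Poses keeping at least 30% of their atoms inside the support (inside
threshold 0.3 and 80 000 positions by default) are scored
by cross-correlation and greedily clustered at 4° / 3 Å tolerances, with
clusters ranked by their best member.

Uniform pose sampling alone cannot land within a 4° cluster tolerance at
tractable sample counts — the rotation ball of 4° occupies a ~1e-5
fraction of SO(3) — so the library is built in stages. First, the joint
rotation/translation samples are scored and greedily clustered. Second,
candidate centres are identified as local maxima of the map (blob centres
are local maxima; superposition bridges between blobs are saddles) and
each centre is re-scanned with a dense deterministic rotation set under a
cheap objective, the mean map density at the rotated atom positions; the
best few rotations per centre are refined immediately, because a body's
centroid rarely coincides exactly with its blob's density peak and at a
few Ångström of offset raw correlation misranks rotation modes. Third,
the top cluster exemplars are polished by the same deterministic pattern
search on the correlation (axis rotations and axis shifts with halving
step sizes), with the refinement budget spread spatially so that one
region's smooth fits cannot starve the others. Empirically the pattern
search converges from ≥ 60° away on the synthetic bodies, which makes the
effective basin large enough for a few thousand sampled poses to recover
planted placements.

## Annealing

`annealFit()` runs Metropolis Monte-Carlo over per-body poses: a move
either jumps to a random library exemplar or perturbs the current pose
locally (defaults 5°, 2 Å). The default schedule is the six-stage
regime used for the trains — temperatures 75000, 30000, 10000, 5000, 1000, 300 with
1000, 800, 800, 500, 500, 300 steps. Temperatures are unitless energy
scales on the weighted total score; the default values correspond to
score magnitudes of the original train-fitting problem (totals of order
1e4–1e5). The package's synthetic toys have totals of order 1e2, so the
recovery studies in the tests run the same six-stage regime with the
temperatures scaled by 1e-3 — same shape, same step counts, energy scale
matched to the problem. By default the
configuration is seeded greedily — each body in turn takes the library
exemplar minimising the partial configuration score given the bodies
already placed — and the best configuration found is polished by a final
deterministic pattern search on the total score. Fixed seeds make runs
bit-reproducible, and with local moves disabled (which also disables the
final search) the search space is exactly the exemplar grid, which is how
the tests enforce the exhaustive-enumeration oracle bound.

## Convergence diagnostic

`scoreHistogram()` reproduces the score-distribution convergence check:
with ≥ 30 independent run scores, the verdict is "converged" iff the best
5% of scores sit below the mean of the remaining mass by more than two of
its standard deviations *and* are separated from it by a gap of at least
half that standard deviation. The gap condition is load-bearing: the
lowest 5% of a pure Gaussian sample already sits slightly more than two
(truncated) SDs below the rest, so the mean condition alone would label a
structureless, near-Gaussian score distribution "converged". The verdict
is invariant under positive rescaling of the scores.

# The synthetic two-state generator

The generator is the package's study system, not a test fixture; its
defaults encode the geometry the pipeline is meant to exercise:

* **Composition**: each repeating unit is one IFTA complex (two elongated
  lobes, IFTA1/IFTA2) plus two IFTB complexes (two compact lobes each,
  IFTB1/IFTB2) — the 2:1 IFTB:IFTA stoichiometry. Default 5 units,
  50 Cα beads per chain. Pseudo-domains are Cα-only beads: the distance,
  accessibility and fitting logic need geometry, not chemistry.
* **Compact state A**: IFTA complexes perpendicular to the polymer axis at
  a 115 Å repeat; IFTB complexes in a separate stacked sub-polymer at a
  65 Å repeat (the 11.5/6.5 nm repeats).
* **Extended state B**: units every 225 Å — a 450 Å (~45 nm) visible
  repeat shared by 2 units — with the IFTA lobes forming a continuous
  central thread parallel to the axis. Each unit is internally 2-fold
  symmetric about an axis perpendicular to the polymer axis (IFTA2 and the
  outer IFTB complex are the C2 images of IFTA1 and the inner one), so the
  whole train maps onto itself under a single C2 operation; the generator
  guarantees this exactly before noise, and `checkC2Symmetry()` verifies
  it by nearest-atom RMSD. Unit extents overlap enough that a central unit
  contacts four neighbours, as in the extended train's contact graph.
* **Cross-links**: candidate residue pairs are classified in both states
  by an independent plain-loop brute force over all copy pairs, then drawn
  from the four (satisfied-in-A × satisfied-in-B) buckets to hit the
  requested per-state satisfied fractions *exactly* (defaults 0.80 / 0.95
  — most links consistent with both states, a surplus of extended-state
  contacts). Planted distances keep a ≥ 5 Å margin from the threshold so
  that 1 Å coordinate noise cannot flip a classification; distances are
  constructed, not sampled, so the noise-free truth is exact.
* **Confidence**: 10% of residues, in one contiguous segment per chain,
  get pLDDT 30 (flexible); the rest 90.
* **Occlusion planting** (`plantOcclusion()`): a blocking pseudo-domain is
  docked onto one face of a chosen chain — cap beads along every open
  face-ward direction at one bead diameter + 1 Å, too close for the probe
  and too dense to leave channels. The planted occluded list comes from a
  shadowing oracle that recomputes accessibility with plain loops,
  independent of the production SASA code: a bead is planted iff it is
  clearly accessible (open-direction fraction ≥ 0.27) and the majority
  (55%) of its exposure faces the block. The thresholds were fixed while
  designing the construction so that the planted set is exactly what the
  block genuinely takes away.
* **Fit cases** (`generateFitCase()`): rigid bodies are three-arm stars
  with unequal orthogonal arms and a bounded ~35 Å extent — extra beads
  thicken the arms as parallel strands instead of lengthening them, and
  arm lengths get a small per-body jitter. Each choice is deliberate:
  compact coils are rotationally featureless once blurred to 15–30 Å,
  which would make rotation recovery ill-posed; unbounded arms would let
  a large body interpenetrate its neighbours' density, which corrupts
  every per-body fit score; and identical shapes would make the
  multi-body assignment depend only on restraints. Consecutive bodies are
  kept within cross-linking range (nearest beads ~25 Å) without steric
  overlap.

## What the generator does and does not emulate

It reproduces the *structural logic* of the problem: multi-copy ambiguity,
two-state distance changes, state-specific burial, low-confidence
segments, C2 symmetry, 15–30 Å density. It does not emulate sequence
realism, side chains, membrane or microtubule context, spectral-level
identification noise, or false-positive cross-links. A green synthetic
suite therefore demonstrates that the *computations* are correct under
known ground truth — not that any particular real dataset is clean.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run, per invocation: 100
random assemblies for the distance oracle; 5-unit (1500-bead) polymers for
validation and geometry; 1-unit (300-bead) polymers for SASA work;
fit libraries of 2500–5000 positions and annealing with the six-stage
regime at reduced step counts (e.g. 100/80/80/50/50/30) for the recovery
studies — sizes chosen so the whole suite completes comfortably on a
single CPU while keeping every recovery statistically meaningful.
Other numerical conventions: coordinates are Å throughout; mmCIF output
carries 4 decimal places (round-trips well under the 1e-3 Å assertion);
MRC maps are written mode 2 (float32), x fastest; Gaussian truncation at
3.5σ keeps per-atom mass errors below 1%; ties in greedy clustering
resolve in score order, which is deterministic because the sampling is.

# Known limitations

* Absolute score magnitudes are meaningful only within one problem; only
  score orderings and the convergence shape transfer between problems
  (hence the temperature rescaling above).
* The excluded-volume count form is coarse; switching to a penetration-
  weighted form changes absolute totals but not the recovery behaviour on
  the synthetic cases.
* SASA reference maxima for non-standard residues fall back to the mean
  reference, and coarse-grained beads use a single radius.
* The CLI and pipeline work on one model pair at a time; no batching.
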