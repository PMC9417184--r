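---
title: "Methods: determining and engineering the oligomeric state of homomeric enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: determining and engineering the oligomeric state of homomeric enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoshift)
```

## The problem

Form II RuBisCO and many other homomeric enzymes are built from one core
dimer that can assemble further into tetramers (a dimer of dimers) or
hexamers (three dimers in D~3~ symmetry). Which state a given homolog adopts
in solution is assigned experimentally by size-exclusion chromatography
coupled to small-angle X-ray scattering and multi-angle light scattering
(SEC-SAXS-MALS): the scattering curve carries the shape of the assembly, and
the light-scattering mass constrains the subunit count. Conversely, the
state can be *engineered*: a handful of substitutions at the inter-dimer
interface can convert a dimer into a hexamer.

`oligoshift` implements that computational workflow end to end:

1. a tidy coordinate model for PDB structures with a chain-to-group
   partition (which chains form which dimer);
2. derivation of a symmetry definition (rigid transforms reference subunit
   -> all positions) and its application to build assemblies;
3. an interface atlas: contacts, hydrogen bonds, salt bridges, and
   interface-residue identification by two geometric criteria;
4. theoretical SAXS profiles by the Debye formula, Guinier analysis, and
   scale-optimal chi fitting for state classification;
5. a combinatorial interface-mutant screen ranked by a surrogate
   interaction score and assessed by interface hydrogen bonds;
6. derived kinetics from the carboxylase/oxygenase specificity relation;
7. seeded synthetic-data generators so every stage is testable without
   downloading structures.

## Coordinate model and conventions

Author residue numbering from the deposited PDB file is canonical
throughout; positions such as 98 or 131 refer to author numbers. Hydrogens,
waters and ligand HETATM records (e.g. the active-site inhibitor CABP) are
excluded from all geometric analyses by default — the distance criteria
below are heavy-atom scales, and typical deposited structures lack
hydrogens. Alternate conformations are resolved to the highest-occupancy
conformer (ties: alphabetically first). Non-standard residues map to `X` in
one-letter sequences, except selenomethionine, which maps to `M`. Only
PDB-format input is supported; the chain partition survives round trips via
`REMARK 300 GROUP` lines.

## Symmetry derivation

`derive_symmetry()` superposes the reference chain's CA atoms onto every
other chain by least squares (Kabsch, via SVD), residues matched by order
for equal-length chains and by global sequence alignment otherwise. Real
crystal structures are only approximately symmetric, so each per-chain RMSD
is reported and checked against a 2.0 Å tolerance that separates genuine
symmetry mates from wrong chain pairings. The point-group label (C2, D3,
...) is inferred from the transform count and the folded rotation-angle
multiset; it is reported, never enforced. At least 20 matched CA atoms are
required per chain, and chains must share at least 70% sequence identity
(the pipeline targets homomers).

## Interface criteria and cutoffs

A residue is *interfacial* when either

* **proximity**: any heavy atom lies within 5.5 Å of any heavy atom of the
  opposite group, or
* **orientation**: its side-chain centroid is within 9 Å of the nearest
  opposite-group heavy atom *and* the angle between CA-to-centroid and
  CA-to-that-atom is at most 90 degrees.

The orientation rule operationalizes "the side chain points at the opposite
subunit"; the 90-degree threshold is the natural half-space reading and is
configurable. The 9 Å distance is anchored at the side-chain centroid, the
natural single-point locator of a side chain. Hydrogen bonds are defined by
distance only — a donor-capable N/O against an acceptor-capable N/O within
3.6 Å, typed by a fixed residue-specific atom-name table without hydrogens
or angular terms. Salt bridges pair Arg/Lys/His charged-group atoms with
Asp/Glu carboxylates within 4.0 Å, a standard literature value. In coarse
two-bead models the single `SC` pseudo-atom inherits the polar capabilities
of its residue type. All cutoffs live in `oligoshift_config()`. Whether the
original criteria counted hydrogens is unknowable from distance cutoffs of
this scale; we use heavy atoms only.

Percent identity is computed from a global alignment (BLOSUM62, gap open
10, gap extend 0.5) as identities over aligned ungapped columns — the
convention is stated because published identity figures rarely name theirs.

## SAXS: Debye profiles, Guinier analysis, chi fitting

Theoretical curves use the orientationally averaged Debye sum
$I(q) = \sum_i \sum_j f_i f_j \,\mathrm{sinc}(q r_{ij})$ with constant form
factors: per-residue electron counts at residue granularity (one scatterer
per residue at its heavy-atom centroid; the default, keeping the O(n²)
distance set desk-sized) or per-atom electron counts at atom granularity.
Hydration-layer and excluded-volume corrections are deliberately omitted:
classification among candidate oligomers rests on shape, which the vacuum
Debye sum captures. Consequences: absolute intensities are arbitrary (the
chi fit optimizes a multiplicative scale) and fine high-q features are not
meaningful.

The Guinier fit estimates R~g~ from
$I(q) = I(0)\exp(-q^2 R_g^2/3)$ on a deterministic low-q window: start from
the 10 lowest-q positive points, grow one point at a time, refit each step,
and stop when either $q_{max} R_g$ would exceed the 1.5 validity limit or
the RMS log-space misfit exceeds three times the initial window's RMS
(floored at 10^-4^). The second guard matters: extending greedily to the
validity limit biases a uniform sphere's R~g~ upward by about +2.4%
(measured on the analytic sphere form factor), because curvature beyond the
Guinier regime steepens the fitted slope; with the misfit guard the
residual bias on an exact sphere is about +0.4%, while noisy data — whose
initial-window RMS reflects the noise — still extend to the full limit.

The chi fit interpolates the model curve linearly onto the experimental q
grid (no extrapolation), solves the weighted least-squares scale in closed
form, and reports $\chi = \sqrt{\sum r_i^2 /(N-1)}$ with residuals
$r_i = (I_{exp} - c\,I_{model})/\sigma$ and $\sigma = 1$ when uncertainties
are absent (then chi is a unitless residual norm, not a reduced chi).
Only the scale is fitted — no constant background term — which is stated in
every report since published fits do not always say which was used.
`classify_oligomer()` calls the candidate with minimal chi and, when a
measured mass and subunit mass are given, checks it against
`round(mass / subunit_mass)` subunits. SEC frames with uniform Guinier R~g~
(within 5% of the run median — our default, as the tolerance used with
instrument-side software is not published) are merged pointwise with
standard-error noise reduction.

## The 2-to-6 design screen

Candidate sites are interfacial template positions where the candidate
homolog's aligned residue differs. Every subset of the k sites (2^k^
candidates, binary-counter order, wild type included) is built by grafting
the template residue onto the candidate subunit and replicating it under
the template symmetry, so each symmetry copy carries the mutations.

Each candidate is scored `n_samples = 50` times; per sample, side-chain
pseudo-atoms within 12 Å of any mutation site receive Gaussian jitter
(sigma 0.3 Å — our stand-in for the conformational sampling breadth of an
all-atom relax protocol, which has no direct equivalent at this
resolution). The score is a transparent surrogate, not a physical energy:
over cross-group heavy-atom pairs within 8 Å it sums a repulsion-only
soft core `clash * ((3.0/d)^8 - 1)` below 3.0 Å, `-1` per hydrogen-bond
pair within 3.6 Å, and `-2` per salt-bridge pair within 4.0 Å (weights in
`surrogate_weights()`). A repulsion-only core was chosen over a full
Lennard-Jones well so that every reward is attributable to a named
interaction — a fixture with one planted hydrogen bond and no clashes
scores exactly minus the hydrogen-bond weight, which keeps the score
hand-checkable. The score is pluggable; nothing downstream depends on its
form beyond "lower is better".

Candidates are ranked by their best (lowest) sample score; the top 5
finalists are assessed by the interface hydrogen-bond count of their best
sample, and the finalist with the most bonds is selected. Published
protocols of this shape end in manual inspection and are ambiguous about
whether "the five best samples" means samples or mutants; we assess the
top-5 *mutants* by their best sample and fully specify the tie-break
(H-bonds, then score, then binary index) so the screen is a pure function
of inputs and seed — byte-identical reports on repeat.

## Synthetic data: what it emulates, what it does not

Generators build coarse subunits of 60 pseudo-residues (CA plus one `SC`
pseudo-atom at an idealized per-residue centroid distance) packed in a
13 Å sphere with 3.5 Å minimum separation, then replicate them under exact
C2, tilted dimer-of-dimers, or D3 transforms (ring radius 13.5 Å, dimer
offset 12 Å). Packing is *image-aware*: a bead is rejected if any symmetry
image of any atom would come within 3.0 Å, which makes assemblies
clash-free by construction while letting subunit surfaces meet tightly
enough to present realistic interfaces (roughly 10-20 interfacial residues
per chain across a D3 inter-dimer interface, the scale seen in real
inter-dimer contacts). The dimer-of-dimers `tilt_angle` (default 30
degrees) tilts the two dimer axes; zero recovers the parallel,
octamer-core-like arrangement. Noise on simulated curves is multiplicative
Gaussian at constant relative level (default 2%, matching well-merged
SEC-SAXS curves); Poisson counting statistics are not modelled.

Passing tests on these fixtures demonstrates the geometry, scattering and
screening machinery on bodies whose ground truth is known exactly. They do
not demonstrate performance on real data: coarse beads have no fold, no
correlated side-chain packing, no solvation layer, and interface chemistry
enters only through residue-typed pseudo-atoms. The kinetics module, by
contrast, operates directly on measured parameter tables.

Every generator is a pure function of its spec and seed and restores the
caller's RNG state.

## Numerical choices and degenerate inputs

* Superposition uses SVD with a determinant flip to exclude reflections;
  fewer than 3 points or collinear points are errors.
* The Debye sum handles q = 0 via the sinc limit; empty models are errors.
* Guinier fitting requires at least 5 usable points and positive
  intensities in the starting window.
* Derived kinetic values are held at full precision internally and rounded
  half-up only at report time (2 decimals for turnovers and ratios, whole
  percent for decreases), matching how such tables are printed. The derived
  oxygenase turnover is computed from the mean parameters, as per-replicate
  raw data are not part of the inputs.
* Enumeration refuses more than 2^20^ combinations; duplicate site
  positions are errors.
* Empty interfaces score 0 with a warning rather than an error, so a
  screen over a disconnected geometry degrades visibly instead of halting.

## Problem sizes

The test suite and the reproduction script run entirely on synthetic
fixtures sized for a single desk CPU: 60-residue subunits (360-residue
hexamers), 150-200 point q grids, 100 classification trials at 2% noise,
and one full 128-candidate screen at 50 samples per candidate. These sizes
were chosen so the whole suite completes in a few minutes while every code
path — packing, symmetry, interfaces, scattering, screening — is exercised
at meaningful scale.

## Known limitations

* The Debye sum is vacuum-only; chi values against real measured curves
  will differ from those of hydration-aware predictors, though candidate
  *ranking* by shape is robust in our trials.
* The surrogate score cannot predict folding, stability, expression or
  true binding energetics; it ranks geometric complementarity of planted
  polar contacts.
* Side chains after mutation are single pseudo-atoms along the existing
  CA-to-side-chain direction (outward from the chain centroid when the
  wild type was glycine); no rotamer search is performed.
* mmCIF input, crystallographic symmetry expansion, P(r) inversion and ab
  initio shape reconstruction are out of scope.
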