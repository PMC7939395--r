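---
title: "Methods: pharmacophore screening and NMR analysis of a dimerization interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore screening and NMR analysis of a dimerization interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartwheel)
```

# The scientific problem

SAS-6 proteins oligomerize into the nine-fold-symmetric cartwheel that
templates centriole assembly. Oligomerization is driven in part by a weak
(Kd of tens of micromolar) self-association of the N-terminal head domain,
in which the β6-β7 loop of one monomer — with a single key hydrophobic
residue at its tip — inserts into a hydrophobic pocket of the other. A small
molecule occupying that pocket blocks head-domain dimerization and hence
oligomerization. This package implements the computational side of finding
such molecules: deriving a pharmacophore from the interface, screening
conformer libraries against it, detecting and localizing binding by NMR
chemical-shift perturbation, estimating affinity from titrations, and
characterizing binding poses from simulation frames.

# The pharmacophore engine

## Model derivation

`deriveModel()` treats the interface loop (a Pro-Ile-Ser-Lys-style
tetrapeptide in the natural dimer) as the "ligand" and the partner monomer
as the receptor, and emits:

* **hydrophobic** features at per-residue centroids of apolar ligand
  side-chain heavy atoms within 4.5 Å of receptor apolar atoms;
* **donor** features at ligand N–H/O–H hydrogens whose heavy atom lies
  within 3.5 Å of a receptor acceptor, directed at that acceptor;
* **acceptor** features at ligand O (or hydrogen-free N) atoms within
  3.5 Å of a receptor donor, directed at that donor;
* **exclusion** spheres, with element van der Waals radii, on receptor
  heavy atoms within 5 Å of the ligand.

Same-kind features closer than a minimum feature distance (default 1.5 Å,
the one derivation parameter stated by the original protocol) are merged to
their centroid with the larger radius. The 4.5 Å hydrophobic and 3.5 Å
hydrogen-bond ranges are standard contact definitions; the source protocol
does not state its own, so both are exposed as configuration.

Tolerance radii default to 1.5 Å for hydrophobic/aromatic and 1.0 Å for
donor/acceptor features; hydrogen-bond directions must agree within 45°.
These defaults are choices of this package — the commercial screening
software used originally does not document its values — and all are
arguments.

## Sub-models and the mandatory core

The original screen used 100 manually chosen combinations of at least five
of ten features, always retaining two hydrophobic/aromatic features at the
pocket plus one donor. The manual choice is unrecoverable, so
`enumerateSubmodels()` instead enumerates *all* subsets of size ≥ 5 that
contain the mandatory core, in deterministic order (size, then
lexicographic), with an optional cap for users who want the historical
budget of 100. For 10 features with a 3-feature core this yields
`sum(choose(7, 2:7))` = 120 sub-models. `defaultMandatoryCore()` encodes
the two-hydrophobic-plus-one-donor rule.

## Fitting and scoring

`fitConformer()` searches all type-compatible injective correspondences
between a sub-model's features and a conformer's typed feature points
(aromatic points may satisfy hydrophobic features and vice versa, mirroring
the mixed aromatic/hydrophobic features of the original model; donors and
acceptors match only their own kind). The search is depth-first with
scarcest-feature-first ordering and is pruned by pairwise-distance
compatibility: a pair may only map onto points whose distance differs from
the feature-pair distance by at most the sum of the two radii. Because
rigid transforms preserve distances, any correspondence surviving the
acceptance test also survives pruning, so the search is exhaustive in
effect; the test suite verifies equality with an unpruned enumeration
using an independent superposition routine.

Each complete correspondence is solved by closed-form least-squares rigid
superposition (Kabsch, via SVD; proper rotations only). A fit is accepted
when every matched point lands within its feature's radius, directional
features agree within the angular tolerance, and no ligand heavy atom
enters an exclusion sphere (a clash excludes the pose from ranking
entirely). The score of an accepted fit is

$$\mathrm{score} = \sum_{\text{matched}} \exp\!\big(-d^2 / (2 (r/2)^2)\big),$$

with d the residual center distance and r the feature radius. The
commercial "fit value" is proprietary; this Gaussian-overlap form was
chosen because it is bounded by the matched count, equals it exactly at
zero residual, and decreases strictly and smoothly as geometric agreement
degrades — properties the test suite asserts directly. `screenLibrary()`
takes the best fit per compound over conformers × sub-models and ranks by
score, breaking ties by compound id for determinism.

# Library preparation

`computeProperties()` uses a standard-valence implicit-hydrogen model
(C 4, N 3, O 2, S 2, halogens 1, charge-adjusted for N/P and O/S);
hydrogen-bond donors are N/O/S atoms carrying at least one hydrogen,
matching the OpenBabel-style counting of the original filter, and aromatic
rings are smallest rings whose bonds are all aromatic (Kekulé-drawn
benzene rings are perceived). The filter bounds (300–500 Da, ≥ 1 donor,
≥ 1 aromatic ring) are inclusive.

Fingerprints are deterministic circular (Morgan-style) environments of
radius 2 hashed into 2048 bits — the de-facto standard family for Tanimoto
diversity work; the original does not name its fingerprint. Diversity
selection is the greedy leader algorithm: walk the ranked list, keep a
molecule iff its similarity to everything already kept is strictly below
the threshold (default 0.6, configurable; the original threshold and its
subsequent manual visual inspection are unstated, and manual curation is
out of scope).

# NMR chemical-shift perturbation

`combinedCSP()` implements
$\Delta\delta = \sqrt{(\delta_H^2 + 0.14\,\delta_N^2)/2}$ — the empirical
amide weighting in which the 15N contribution is scaled by 0.14.
`cspProfile()` matches peaks across conditions by assignment label (the
original transferred assignments by overlaying spectra; automated peak
tracking is deliberately not attempted) and flags residues as notable when
$\Delta\delta > \max(2\sigma, 2\sigma_{exp})$, with σ the standard
deviation over *all* matched residues (no outlier trimming — whether the
original trimmed is unstated, so the simplest rule is used and documented)
and σ_exp = 0.01 ppm, the intrinsic error implied by typical spectral
digital resolution.

`fitTitration()` assumes a single-site 1:1 interaction in fast exchange —
consistent with peaks that move continuously with ligand concentration —
and fits the exact quadratic-root isotherm with a global Kd and
per-residue Δδmax by bounded Levenberg–Marquardt least squares
(minpack.lm), multi-started from Kd = 10 µM, 1 mM and 100 mM with bounds
[0.1 µM, 1 M]. The saturation flag is false when the fitted Kd exceeds the
highest ligand concentration: a titration that never passes its Kd cannot
have approached saturation. With five concentrations spanning 0.125–2 mM
and eight site residues, a planted Kd of 2 mM is recovered within a few
percent at the 2 % noise level and to machine precision without noise
(identifiability of the exact model), which the acceptance checks
exercise.

`mapToStructure()` writes Δδ into the B-factor column (unmatched residues
0) so any molecular viewer can color by perturbation, and quantifies site
localization: the fraction of notable residues whose Cα lies within
8 Å (configurable) of any site-residue Cα, plus a one-sided
hypergeometric probability of that overlap arising by chance. The
classification used by the pipeline is "site binder" at fraction ≥ 0.5,
"off-site binder" below, "non-binder" when nothing is notable — mirroring
the three experimental outcomes (pocket binder / off-pocket binder /
non-binder). `compareHetNOE()` declares "no significant change" when no
residue's difference exceeds 3× its propagated uncertainty; the original
reports only a qualitative verdict, so the 3σ rule is this package's
stated criterion.

# Trajectory analysis

`ligandRMSDSeries()` superposes each frame on the reference using protein
Cα atoms only, then measures ligand heavy-atom RMSD without refitting, so
genuine ligand motion relative to the protein is reported.
`contactMap()` counts frames in which each (residue, ligand heavy atom)
minimum heavy-atom distance is ≤ 4 Å and normalizes by the maximum count,
so the most frequent contact scores exactly 1. `hbondOccupancy()` uses the
standard 3.5 Å donor–acceptor distance with donor-H···acceptor within 30°
of linear. `poseStability()` maps the qualitative
stable / semi-stable / unstable language onto explicit bounds: stable when
≥ 80 % of frames lie below 2 Å, unstable below 40 %, semi-stable between.
All four cutoffs are configuration; the original figures state none.

# What the synthetic generators emulate — and what they do not

The generators are pure functions of a `SyntheticSpec` (same spec ⇒
bit-identical output; the caller's RNG stream is restored afterwards).

* `makeToyInterface()` reproduces the *geometry class* of the interface: a
  hydrophobic pocket with an apolar loop tip inserted 2.9 Å deep, rimmed by
  a backbone carbonyl accepting two planted hydrogen bonds and an amide
  donating one. Pseudo-residues use idealized positions; no physical
  realism beyond the distances the operators measure is attempted.
* `makeLigandLibrary()` plants binders whose typed feature points sit on
  the model's feature centers (jitter ≤ min(0.3 Å, radius/2)), dressed
  with a consistent molecular graph in which apolar groups stay
  bond-disconnected from each other (so hydrophobic centroids stay put)
  and acceptor oxygens keep their planted lone-pair direction. Decoys are
  random chains with no hydrogen-bond donor, so they can never satisfy a
  donor-containing mandatory core.
* `makeTitrationPeaks()` shifts site residues along the exact isotherm,
  splitting the combined perturbation 1:2 between 1H and 15N (typical
  amide behavior; only the combined value matters downstream), with
  Gaussian noise of sd `cspNoise × ddMax` on the planted perturbation and
  a 0.002 ppm baseline wobble off-site. Defaults are the study conditions:
  0.1 mM protein, 0.125–2 mM ligand, Kd 2 mM, Δδmax 0.15 ppm, 2 % noise.
* `makeTrajectory()` applies rigid-body ligand jitter (≤ 0.3 Å) about the
  pose so planted contacts and hydrogen bonds stay intact in bound frames;
  the two-state mode hops to a 4 Å-displaced pose with bound-state
  occupancy 0.6 (the midpoint of the semi-stable window, so the class is
  unambiguous under binomial noise at 200 frames), and the unstable mode
  ramps the ligand out of the pocket within the first 8 % of frames and
  lets it wander.

Passing tests on these generators demonstrates that the *operators* honor
their contracts (thresholds, normalizations, parameter recovery,
classification boundaries). They do not demonstrate robustness to the
pathologies of real data — peak overlap and assignment errors, conformer
strain, partial occupancy, force-field artifacts — which the generators do
not model.

# Numerical choices and degenerate inputs

* Superposition is the closed-form SVD solution restricted to proper
  rotations; collinear point sets are accepted (the minimizer is valid but
  non-unique) and fewer than three points are an error.
* Alternate locations in PDB input keep the highest-occupancy conformer
  (ties: first in file); insertion codes are folded into residue identity.
  Heavy atom means element ≠ H/D everywhere.
* Cross-structure residue pairing uses global sequence alignment of
  CA-bearing residues (BLOSUM62, no end-gap penalties); the original's
  alignment and residue-subset protocol for its RMSD figures is unstated,
  which is why cross-species comparisons carry a tolerance band rather
  than an exact target, and both candidate reference structures are
  accepted as inputs.
* An empty interface yields an empty model with a warning, not an error;
  an all-zero titration returns a "no binding detected" status; a
  contact-free map is all-zero with an explicit status instead of a 0/0
  normalization.
* Ranking ties break by compound id; sub-model order is size-then-
  lexicographic; all outputs are written with fixed formatting so reruns
  are byte-identical.

# Problem sizes

The shipped tests and acceptance script use 21-compound libraries
(1 planted binder + 20 decoys, 3 conformers each) over 20 seeds,
60-residue titrations over 10 seeds, 200-frame trajectories over 10 seeds
per mode, 100 random fit-oracle cases and a 10°-coarse SO(3) grid oracle.
These sizes make every oracle comparison exhaustive while keeping the full
suite under a minute; all counts scale through `SyntheticSpec` and
function arguments.

# Known limitations

* Conformers are fitted rigidly; no on-the-fly ligand relaxation.
* Docking pose generation and MD production are out of scope — trajectory
  frames and poses are inputs.
* Aromaticity perception covers explicit aromatic bonds and Kekulé
  six-rings only; exotic heteroaromatics should arrive with explicit
  aromatic bond orders.
* Peak matching is assignment-based; spectra with unassigned or ambiguous
  peaks need external assignment transfer first.
* The hypergeometric site-enrichment test treats residues as exchangeable,
  ignoring spatial autocorrelation along the chain; its p-value is a
  ranking aid, not a calibrated error rate.

# Session info

```{r}
sessionInfo()
```
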