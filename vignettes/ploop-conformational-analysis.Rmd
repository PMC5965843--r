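---
title: "Methods: conformational comparison and kinetics of P-loop phosphatases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational comparison and kinetics of P-loop phosphatases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploopflex)
```

## Scope and model

`ploopflex` analyses the conformational switch of phosphate-binding loops
(P-loops) in dual-specificity phosphatases and the kinetic consequences of
that switch. The package works from heavy-atom coordinates (X-ray models
carry no hydrogens) and from progress-curve assay tables. It does not
refine structures, run dynamics, or score alignments against databases;
those are upstream of its remit.

The structural half of the package rests on four primitives:

1. **Kabsch superposition.** Given paired coordinate sets, the
   least-squares optimal rotation is obtained in closed form from the SVD
   of the cross-covariance matrix, with the determinant correction that
   excludes reflections. Region RMSDs are reported *in the global frame*
   by default — when a paper says a loop deviates by some RMSD "when the
   structures are superimposed", the loop is not re-fitted, and neither do
   we (a `refit` flag gives the locally re-fitted alternative).

2. **Residue correspondence with iterative trimming.** "N structurally
   aligned residues" style counts come from a protocol, not a fact of
   nature. Ours: global sequence alignment (BLOSUM62, affine gaps, open
   10 / extend 0.5) proposes Cα pairs; superposition is then repeated,
   discarding pairs deviating by more than twice the current RMSD (with a
   2.0 Å floor, so well-fitting structures are not trimmed to nothing),
   for at most 10 cycles. The floor and multiplier are conventional;
   counts produced by any reasonable protocol of this family agree to a
   few residues, which is why downstream checks treat aligned-residue
   counts with tolerances rather than exactly.

3. **Backbone torsions.** φ/ψ/ω via the standard atan2 construction,
   IUPAC sign convention, range (−180°, 180°]. Torsions are suppressed at
   termini and across chain breaks, a break being a consecutive Cα–Cα
   distance above 4.5 Å — the generous threshold tolerates distorted
   geometry while catching unmodelled gaps.

4. **Pseudo-hydrogen amide directions.** The orientation of a backbone
   amide N–H (the quantity that distinguishes an active from an inactive
   P-loop) is taken opposite to the bisector of the N→CA and N→C(i−1)
   unit vectors: standard planar-amide geometry, no force field needed.

## P-loop state calls

For a signature motif HCxxGxxR starting at residue *m*, the four central
residues (*m*+3 … *m*+6 — the Gly95–Gly98 window when the motif histidine
is 92) are scored by the cosine between the amide direction and the
direction from N to the pocket centre. The pocket centre defaults to the
centroid of a hetero ligand found within 8 Å of the motif (vanadate,
formate, or a buffer molecule occupying the pocket); with no ligand the
Sγ of the catalytic cysteine is used, and the choice is recorded in the
output. The call is `active` when the mean cosine exceeds +0.2 with at
least 3 of 4 residues individually above it, `inactive` under the mirror
condition, `indeterminate` otherwise. The ±0.2 margin encodes "towards
vs. away" with a guard band against coordinate noise; a cosine of 0.2
corresponds to ≈78°, so only orientations clearly on one side of
perpendicular count. The margin is symmetric because nothing in the
geometry privileges one direction.

## Peptide-flip detection

A peptide-plane flip barely moves the Cα trace — which is precisely why it
needs a dedicated detector. Residue *i*'s carbonyl is compared between
conformers after superposing the four flanking Cα atoms (i−1 … i+2); the
statistic is the angle between the two C=O unit vectors. A genuine flip
approaches 180°, ordinary loop adjustment stays far below 90°, so the
threshold sits at 90° where the two regimes are best separated. The
synthetic flip generator rotates the C(i)/O(i)/N(i+1) peptide unit 180°
about the Cα(i)–Cα(i+1) axis; because both anchors lie on the axis the
chain stays closed, and the measured carbonyl rotation on ideal-geometry
fixtures comes out near 160° (the C=O vector is not exactly perpendicular
to the rotation axis), comfortably past threshold.

## Ramachandran regions

Classification is polygon membership against a versioned, coarse region
file (`extdata/rama_regions_v1.csv`): general favored (α and β), general
allowed (broad negative-φ band plus the left-handed helix), and
glycine-only regions covering the positive-φ/extended territory forbidden
to side-chain-bearing residues. The contract is a deterministic label from
(φ, ψ, residue type), not a probability density — the scientific claim the
label supports is of the form "this conformation is accessible only to
glycine", which coarse polygons capture robustly. The polygons are
deliberately simple rectangles; refining their edges would change borderline
labels but not that claim.

## Hydrogen bonds and packing contacts

Hydrogen bonds use a permissive heavy-atom criterion suited to
hydrogen-free models: donor–acceptor distance ≤ 3.5 Å and, for every heavy
atom covalently bonded to the donor, an antecedent–donor–acceptor angle
≥ 90° (no acceptor-angle term). Network differencing matches bonds by
donor/acceptor residue number plus atom name, partitioning into
only-in-A / only-in-B / shared.

Packing contacts count carbon–carbon atom pairs between a residue's
side-chain carbons (CB outward) and carbons of any other residue of the
chain within 4.5 Å. The default convention is the most literal one —
unordered atom pairs, partner carbons from backbone or side chain,
sequence neighbours *not* excluded — and because published counts rarely
state their convention, the same call can report distinct-partner-atom
and neighbour-excluded variants so a printed number can be located among
them. An `exclude_hydrophilic` flag removes the carbons of hydrophilic
functional groups (imidazole, guanidinium, carboxylate, amide) for
hydrophobic-packing comparisons.

## Kinetics

Initial velocities are the least-squares slope of product signal versus
time over a 2–10 min window (the first two minutes absorb mixing and
temperature equilibration). Saturation fits use v = Vmax·S/(KM+S) — a Hill
equation with coefficient fixed at 1 is the same model, and a free-Hill
diagnostic fit is available to confirm the absence of cooperativity. Two
estimators are kept deliberately distinct: nonlinear least squares
(Levenberg–Marquardt, starts Vmax₀ = max v, KM₀ = S at half-max by
interpolation, deterministic) and the unweighted Lineweaver–Burk line. On
noiseless data they agree to 1e−6 relative; under noise the
double-reciprocal transform amplifies low-velocity error and the nonlinear
fit has lower KM RMSE — a property the test suite documents at a fixed
seed. Unit chain: Vmax [µM·min⁻¹] / [E] [µM] / 60 → kcat [s⁻¹]; KM in mM;
kcat/KM in s⁻¹·mM⁻¹. Substrate depletion is ignored over the window
(initial-rate assumption); the simulator warns when product exceeds 10% of
S₀, which genuinely happens at high kcat/low S — a caution inherited from
the assay design itself, not a bug in either.

## What the synthetic generators emulate — and what they do not

The generators produce every input the test surface needs without any
download: peptides with ideal bond lengths/angles (versioned table,
Engh–Huber-like values) laid down by natural-extension placement so the
requested φ/ψ/ω are recovered to 1e−6; CB by the tetrahedral L-chirality
construction (improper C-N-CA-CB = −123°); rigid motions with recorded
generating transforms; flip pairs as above; multi-model torsion ensembles
built by rotating about the torsion bond; and assay curves in the
strict initial-rate regime, product = v(S₀)·t, with multiplicative
Gaussian noise (plate-reader-like; additive available) and per-replicate
seed streams (`seed + k − 1`) so replicate *k* is reproducible alone.
Assay defaults are the published study conditions: six DiFMUP
concentrations 50–1500 µM, 10 nM enzyme, readings every 2 min for 10 min.

These fixtures have exact known answers, which is their point — but they
are idealised. Real crystal structures carry coordinate noise, alternate
conformers, unmodelled termini and chain breaks; real assays carry
substrate depletion, inner-filter effects and pipetting error. Passing
tests on fixtures therefore demonstrates the *correctness of the
computations*, not the field behaviour of the thresholds; the
structure-based checks against deposited entries (see the acceptance
tests) exercise the latter and require the deposited coordinate files,
which are not bundled with the package sources.

## Numerical choices and degenerate inputs

- Superposition requires ≥ 3 paired points; collinear sets are solved but
  flagged with a rank warning.
- Torsions error on coincident consecutive points; ±180° is reported as
  one value (+180 by convention of the (−180, 180] range, up to floating
  point at the boundary).
- Ensemble histograms use 36 fixed bins, (a, b] convention so +180 lands
  in the top bin; frequencies sum to 1 within 1e−9.
- Altloc policy on reading: keep the highest-occupancy conformer, ties to
  the alphabetically first altloc — single-conformer geometry is what
  comparative analyses report. Waters are dropped unless requested;
  selenomethionine and similar modified residues stay in the polymer.
- Multi-copy asymmetric units: the default analysis chain is the first
  polymer chain; per-chain runs cover copy-agreement checks.
- Nonlinear fits error (rather than return nonsense) on non-positive
  fitted KM or on fewer than three distinct substrate concentrations.

## Problem sizes used by the test suite

The suite runs entirely on generated data: peptides of 2–20 residues,
ensembles up to 10,000 models for the uniformity check (3σ binomial
envelope per bin), 100-replicate KM-recovery simulations at 1% noise, a
1000-rotation optimality oracle, and brute-force O(N²) contact oracles on
fixtures plus a deposited-format example structure shipped with bio3d.
These sizes make every check exact or statistically decisive while keeping
the default run in tens of seconds.

## Known limitations

- Sequence-adjacent contact conventions, H-bond criteria and Ramachandran
  polygons are field conventions, not fitted quantities; alternate
  reasonable choices shift counts and labels at the margins.
- The iterative-trimming aligned-residue count is protocol-dependent by
  nature (hence tolerance-checked downstream).
- No symmetry expansion: crystal-packing contacts are visible only if
  symmetry mates are supplied as explicit coordinates.
- Kinetic fits assume the initial-rate regime; strongly depleting curves
  should be truncated or modelled upstream.
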