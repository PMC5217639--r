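---
title: "Methods: CDK2 substrate recognition at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDK2 substrate recognition at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdk2substrate)
```

This vignette documents the models, parameter choices and numerical
conventions behind the package, and is explicit about what the
synthetic-data generators do and do not emulate.

## The scientific setting

Cyclin A/CDK2 phosphorylates serine or threonine residues (the P+0 site)
in its substrates. The minimal recognition motif is S/T-P-X-R/K/H: an
invariant proline at P+1, any residue at P+2, and a preference for a
basic residue at P+3 that contacts the phosphorylated activation-loop
threonine of the kinase (pT160) and I270 of the cyclin. The package
quantifies this motif over a curated site table, reimplements the
conformer-selection protocol used when modelling the disordered p27^KIP1^
C-terminal substrate peptide (residues 180–194, NAGSVEQTPKKPGLR), checks
the geometry of modelled kinase–substrate interfaces, and compares
phosphorylation kinetics of wild-type and mutant substrate peptides.

## Consensus statistics

Each curated window (11–15 residues) is anchored on its phosphoacceptor.
The table annotates the site (e.g. T187) but not the anchor position
inside the window, so anchoring applies a deterministic rule: P+0 is the
occurrence of the annotated residue type that is immediately followed by
proline; when several positions qualify, the one nearest the window
midpoint wins, then the leftmost. Requiring the *type* to match resolves
windows like QTPASPARYSPV (an S443 site that also contains a T-P at
index 2), and the midpoint tie-break resolves windows with two S-P
occurrences (e.g. STSASPKKSPPP). The rule is intentionally strict: a
window without a type-matching S/T-P cannot be anchored and errors.

Frequencies at positions P−7..P+7 are normalized per column by the
number of windows covering that position. Windows shorter than the full
±7 span contribute gaps, which are excluded from the denominator rather
than imputed; columns with no observations are all-zero. Logo heights
default to plain frequencies; an information-content mode
(`log2(20) − H` bits per column, heights = frequency × column IC) is
available, with the small-sample bias correction `(20−1)/(2·ln2·n)` off
by default so that column heights are a pure function of the observed
distribution.

The "basic at P+3" statistic is reported at two levels because the
underlying claim is ambiguous between counting sites and counting
proteins: site-level (29/35 ≈ 0.829 on the packaged table) is the
headline number, protein-level (24/27 ≈ 0.889, proteins with at least
one such site) is reported alongside.

## Conformer model selection

`sample_ensemble()` builds peptide backbones from internal coordinates
(NeRF chaining) with ideal geometry: N–CA 1.458 Å, CA–C 1.525 Å,
C–N 1.329 Å, C=O 1.231 Å, omega fixed at 180°. Phi/psi are drawn as
`base + Normal(0, jitter_sd)` per residue, seeded. The build/measure
round trip is exact to well below 1e-3°, which the test suite asserts on
random profiles; this is the invariant that makes the ensemble a valid
test bed for the selection protocol.

`rama_filter()` classifies each residue with both dihedrals defined
against a rectangle-based region table. No authoritative region set is
mandated by the underlying protocol, so the package ships a default
(beta, right-handed alpha and left-handed alpha cores as favored, each
with an allowed margin) as a TSV that can be swapped for stricter
definitions via `read_rama_regions()`. Rectangle boundaries are closed;
angles are wrapped into (−180, 180]. A model passes when the favored
fraction is at or above the threshold (default 0.90, matching the
protocol's "90 % or more").

`select_model()` picks the filter-passing model with the lowest backbone
RMSD to the reference, ties broken to the earliest model. RMSD uses N,
CA, C, plus O where present in both structures, after optimal (Kabsch)
superposition — comparing independently built models in a fixed frame
would be meaningless. The superposition is reflection-corrected
(determinant +1) and is validated in the tests against a brute-force
rotation-grid oracle (20° Euler grid + Nelder–Mead refinement), an
entirely independent route to the same optimum.

Template support uses ungapped sliding identity with the *target* length
as denominator, which is the convention that makes a 10-mer exact
substring of a 15-mer score 67 % and a 5-mer score 33 %. The published
pass count (64 of 200) and selected-model RMSD (1.1 Å) of the original
modelling ensemble are not reproducible — that ensemble was never
published — so the package treats the procedure, not those numbers, as
the deliverable, and verifies each component against independent
recounts and oracles.

## Interface geometry

Hydrogen bonds follow the geometric criterion: donor–acceptor distance
strictly below 3.5 Å and hydrogen–donor–acceptor angle strictly below
30°, the angle taken at the donor between the D–H and D–A directions
(the criterion's literal reading; a `"dha"` option instead scores the
deviation of D–H···A from linearity for users who prefer that
convention). X-ray-style inputs carry no hydrogens, so backbone amide
hydrogens are inferred in the C(i−1)–N(i)–CA(i) plane at 1.0 Å from N,
opposite the bond bisector. Sidechain donors without a placeable
hydrogen are tested on distance only and flagged, rather than silently
dropped — on real structures this keeps Lys/Arg/Ser contacts visible at
the cost of angle specificity.

Salt bridges pair basic nitrogens (Lys NZ, Arg NE/NH1/NH2, His ND1/NE2)
with carboxylate or phosphate oxygens at ≤ 4.0 Å. No cutoff is mandated
by the source protocol; 4.0 Å between charged-group heavy atoms is the
common contact-analysis default and is configurable.

Restraints are ambiguous minimum-distance restraints: a restraint is
satisfied when the minimum heavy-atom distance between its two groups is
at most the ceiling (3.5 Å for contact restraints, 3.0 Å for Mg²⁺
coordination). The shipped default spec encodes the three families used
to drive the docking of the substrate into the catalytic cleft: P+0
hydroxyl ↔ ATP, P+3 ↔ pT160 and P+3 ↔ I270, and Mg²⁺ ↔ its ligands.
Docking itself (rigid-body search, simulated annealing, MD refinement)
is out of scope: the module verifies restraints and interfaces on given
coordinates.

## Kinetics

`fit_michaelis_menten()` fits `v = Vmax·S/(Km+S)` by Levenberg–Marquardt
nonlinear least squares — not a Lineweaver–Burk linearization, which
biases the error structure. Starting values are `Vmax₀ = 1.2·max(v)` and
`Km₀ =` the concentration whose velocity is nearest half-maximal;
convergence tolerance is 1e-10 on the relative parameter change with a
500-iteration cap. Replicates are fitted as independent points. Standard
errors come from the curvature of the residual surface at the optimum.
A flat velocity profile leaves Km unidentified (the optimizer runs into
its positivity bound); such fits are flagged `converged = FALSE` rather
than throwing, and refuse downstream comparison.

`compare_kinetics()` reports Vmax, Km and efficiency ratios with
first-order error propagation. Efficiency is `Vmax/Km`; for the mutant
peptide parameters (Km 81.4 µM, Vmax 1.11 pmol/min) this recomputes to
≈ 0.0136, and the package always reports the recomputed ratio rather
than any externally printed one (for the wild-type parameters the
recomputed value is ≈ 0.0236).

## What the generators emulate — and what they do not

- `sample_ensemble()` emulates a homology-modelling ensemble only in the
  sense that matters to the selection protocol: a seeded population of
  backbones with controllable Ramachandran quality. It has no energy
  model, no sterics, no sidechains.
- `make_complex_fixture()` builds geometric stand-ins, not homology
  models: minimal kinase/cyclin chains carrying exactly the planted
  hydrogen bonds (2.9 Å, near-zero angle), decoys violating exactly one
  criterion each (3.8 Å, or 45°), salt bridges at 3.7 Å (inside the
  salt-bridge cutoff, outside the H-bond one, so the two detectors stay
  separable), and restraint partners at 3.0 Å (satisfied) or 5.5 Å
  (violated). Contacts implied by satisfied restraint geometry (the P+3
  lysine against the phosphothreonine phosphate) are part of the
  fixture's declared ground truth. A contradictory request — a displaced
  peptide that still claims planted contacts — is rejected.
- `simulate_velocities()` draws multiplicative Gaussian noise
  (`cv` defaults to 0.05) around the true curve, truncated at zero, over
  a 2-fold dilution series 12.5–400 µM. The default of 10 measurements
  per concentration mirrors the underlying assay design of five
  independent experiments performed in duplicates. It does not model the
  radioactive capture assay, background subtraction or enzyme-amount
  normalization; "Vmax" is the maximal rate in the assay's units.

Consequently, passing tests demonstrate correctness of the statistics,
geometry and fitting machinery on inputs with known truth; they do not
validate biological realism of any particular structural model.

## Numerical conventions and problem sizes

Angles are degrees in (−180, 180] (IUPAC dihedral sign convention),
coordinates Ångström, residue numbering 1-based; PDB I/O keeps a single
model, drops altlocs other than blank/'A' and ignores insertion codes.
Frequency columns sum to 1 within 1e-9; superposition rotations are
proper within 1e-9; PDB round trips are exact to the format's 0.001 Å.

The test suite exercises the protocol at the sizes the package considers
representative for desk-scale verification: 200-model ensembles for the
filter recount, 20-model ensembles for selection oracles, 20 seeded
datasets × 200 bootstrap resamples for interval coverage (checked as a
one-sided binomial test of the 90 % coverage claim at α = 0.05, which is
the faithful finite-sample encoding of that claim).

## Known limitations

- The anchoring rule is a documented convention; other conventions
  (leftmost match, ignoring residue type) would re-anchor a handful of
  multi-motif windows.
- Gap exclusion at the flanks means outer columns rest on fewer
  observations than central ones; the matrix records `n_obs` so users
  can weight accordingly.
- The Ramachandran rectangles are a coarse stand-in for density-based
  region definitions; swap in a stricter TSV for publication-grade
  filtering.
- Hydrogen inference covers backbone amides only; sidechain-donor
  H-bonds are distance-only.
- The kinetics module assumes initial-rate conditions and homoscedastic
  multiplicative noise; it does not model substrate depletion or
  product inhibition.
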