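---
title: "Methods: conformer, scattering, motif and kinetics analysis of two-lobed sugar kinases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformer, scattering, motif and kinetics analysis of two-lobed sugar kinases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinconf)
```

# Scope and model system

`kinconf` implements the computational half of the characterisation of an
actinobacterial glucosamine (GlcN) kinase family: enzymes with the two-lobed
eukaryotic-protein-kinase fold whose catalytic cycle is driven by a
hinge-bending opening/closure of the N-lobe (an N-terminal cap plus an
intermediate subdomain) against the C-lobe. Four analysis stages are
covered, each usable on its own:

1. **Conformer analysis** — interlobe openness, pairwise RMSD matrices,
   ensemble PCA with porcupine mode vectors, and the hinge axis/angle
   between open and closed states.
2. **Small-angle scattering** — coarse-grained Debye profiles from
   C-alpha coordinates, automated Guinier analysis, and two-state
   (open/closed) volume-fraction fitting of experimental curves.
3. **Motif classification** — PROSITE-style scanning for the family's
   helix-alpha12 consensus signature `Q-x(2)-RE-x(2)-YA-x(3)-LP-x-W` and
   catalytic-loop motif `D-x-H`, with mismatch tolerance and a
   motif-spacing family call.
4. **Enzyme kinetics** — Michaelis-Menten fitting and relative-activity
   normalisation.

A fifth module generates synthetic inputs with machine-readable ground
truth for every stage, so the entire pipeline is testable without any
structure or scattering downloads.

# Coordinate model and subdomain scheme

All structural operations use one scattering/geometry centre per residue
at the C-alpha position, indexed by *author* residue numbering. This is
deliberate: the quantities of interest (interlobe distances, domain
rotations, shape-level scattering differences) are rigid-body and
shape-level, and author numbering is how the reference enzyme's landmarks
are cited (reporter residues 15 and 416, linker 187–193, C-lobe 194–438).
Missing residues are permitted everywhere; ensemble operations work on the
intersection of resolved residue numbers, and pairing across conformers is
by residue number, never by sequence alignment (the members are the same
protein).

`subdomain_scheme()` defaults to linker 187–193 and C-lobe 194–438. The
cap/intermediate boundary within the N-lobe is not enumerated by the
reference structures' description, so the default split (cap 1–95,
intermediate 96–186) is a convention and every range is user-overridable.
The default *mobile* domain for hinge analysis is everything N-terminal of
the linker (residues < 187); the default *alignment* range is the C-lobe
through residue 420, excluding the flexible C-terminal tail.

# Superposition, PCA and the hinge decomposition

Rigid-body superposition is the Kabsch algorithm: SVD of the 3×3
cross-covariance of centred point sets with the determinant correction
that forbids reflections. Degenerate (collinear or < 3-point) inputs are
rejected. `superpose_range()` fits the transform on one residue range and
measures RMSD on another, which is how "superpose the C-lobe, measure the
whole molecule" numbers are produced.

Ensemble PCA superposes every member onto the first over the alignment
range (C-lobe by default), then diagonalises the covariance of the
flattened common-residue coordinates. With few members and many
coordinates the decomposition goes through the members × members Gram
matrix; modes are reported as per-residue 3-vector displacements
(porcupine vectors) and member scores as projections. An ensemble of
identical members is returned as a flagged zero-variance result rather
than an error.

The hinge angle is a two-stage rigid-fit decomposition: superpose the
second conformer on the *fixed* domain, then fit the residual rigid
transform of the *mobile* domain and decompose its rotation into
axis/angle (plus the screw translation along the axis). This is a
two-domain quantity — no automatic dynamic-domain segmentation is
attempted, because the biological question supplies the domains. For a
constructed pure rotation the angle is recovered to numerical precision;
near 0° the `acos` conditioning limits accuracy to about 1e-5 degrees,
and the axis of a near-zero rotation is arbitrary by convention.
Conformational state labels (I, II, ...) are assigned by descending
interlobe distance, not by chain identifier, since deposition order does
not encode openness.

# Scattering model

`debye_profile()` evaluates the orientationally averaged Debye double sum
`I(q) = Σ_ij f_i f_j sin(q r_ij)/(q r_ij)` with a uniform dummy form
factor `f = 1` per residue (compiled kernel; the O(n²) pair-distance set
is computed once). This coarse graining resolves open-versus-closed shape
differences, which is all the two-state analysis needs; atomic form
factors, hydration-layer contrast and P(r) inversion are out of scope. The
default grid is 150 linear points over 0.005–0.35 Å⁻¹, a typical
biological SAXS range.

`guinier_fit()` automates the standard low-angle analysis: iterated
linear fit of ln I versus q², truncating the window until
`q_max · Rg ≤ 1.3` (the globular-particle rule), with a 50-iteration cap,
a minimum of 5 points, and hard errors on non-positive intensities in the
window or a non-decaying profile. `Rg = sqrt(−3·slope)`; the standard
error propagates from the slope's.

`two_state_fit()` solves the σ-weighted non-negative least-squares
problem `experimental ≈ c_open·I_open + c_closed·I_closed + background`
and reports volume fractions `w = c/(c_open + c_closed)`. The free-sign
background is represented as the difference of two non-negative columns
inside a single non-negative solve — an exact reformulation of the convex
problem, not an approximation. The background absorbs buffer-subtraction
residuals and can be disabled. Identical basis profiles are rejected as
unidentifiable. Weighting is 1/σ² when uncertainties are present,
unweighted otherwise.

# Motif grammar and the family call

The pattern compiler accepts dash-separated tokens that are either runs
of literal residues or wildcards `x`/`x(n)` (`x(0)` is a parse error).
The family signature compiles to span 16 with literals Q, R, E, Y, A, L,
P, W at offsets 0, 3, 4, 7, 8, 12, 13, 15 — exactly the conserved
GlcN-contacting and structurally conserved positions along helix alpha-12
when anchored at the glutamine. Scanning tests every window; only literal
positions can mismatch, matching is case-insensitive, and non-standard
letters (B, Z, X, ...) mismatch every literal. All overlapping hits are
reported; deduplication is left to consumers.

The family call requires a full (mismatch-free) signature hit preceded by
a catalytic-loop `D-x-H` hit at a start-to-start gap within 60–160
residues. The spacing rule is this package's own addition: the two motifs
are co-located structurally in the reference enzyme (catalytic loop at
300, signature at 405, gap 105), but no sequence-distance rule was ever
stated for the family; the default window brackets the reference gap with
room for family-scale indels, is overridable, and can be disabled
entirely (`require_catalytic = FALSE`). A known partial matcher — the
signature with its tyrosine replaced by alanine — is correctly reported
at one mismatch and excluded from the strict family call.

# Kinetics

`mm_fit()` fits `v = Vmax·S/(Km + S)` by Levenberg-Marquardt with
data-driven initialisation (`Vmax₀` = maximum rate; `Km₀` = concentration
at half-max by interpolation), replicate averaging with SD weights when
replicates are present, and standard errors from the local curvature. No
Hill or substrate-inhibition extensions are offered — the family's
saturation data are plain Michaelis-Menten. When the fitted Km exceeds
the sampled concentration range (the glucose regime, Km > 100 mM, sampled
well below saturation) the fit warns and flags the result: in that regime
Km and Vmax are individually poorly determined even though their ratio is
not. `relative_activity()` performs the reference-substrate
normalisation used for substrate-preference panels.

# What the synthetic generators emulate

`make_hinge_ensemble()` builds a two-domain C-alpha decoy: each domain is
a seeded self-avoiding walk with 3.8 Å virtual-bond steps, a 3.0 Å
non-bonded clash floor, and a protein-density bounding sphere
(radius ≈ 3.2·n^(1/3) Å); the mobile domain is rigidly rotated about a
fixed hinge axis by each requested angle. The mobile domain sits at a 45°
kink relative to the hinge axis so that rotation swings it *toward* the
fixed lobe — closure compacts the particle (the generated open/closed
pair shows a Guinier Rg drop of ~1.7 Å), reproducing the experimentally
observed phenomenology of closure rather than a neutral azimuthal swing.
Defaults are the study conditions: six conformers spanning a 23.8° hinge
rotation with domain sizes of 186 (N-lobe analogue, residues 1–186) and
245 (C-lobe analogue, residues 194–438), and reporter residues mirroring
positions 15 and 416. Configurations with interdomain clashes or a
non-monotone reporter-distance series are regenerated deterministically
(bounded retries under the same seed stream).

What the decoy does *not* emulate: secondary structure, side chains, a
real linker (the seven linker residues are left unmodelled rather than
placed unrealistically), crystallographic coordinate error, and lobe
asymmetry in internal flexibility. Passing tests therefore demonstrate
the correctness of the estimators on clean rigid-body ground truth — not
robustness to the internal deformations real conformers superimpose on
the hinge motion.

`make_saxs_mixture()` mixes the two Debye basis curves and applies
multiplicative Gaussian noise (the σ column records the generating SD).
`make_motif_set()` plants signature windows — background kept at wildcard
positions, literals overwritten, degradations applied at randomly chosen
literal positions — in i.i.d.-uniform random sequences, a deliberately
featureless background (real proteomes have composition bias).
`make_kinetics_set()` draws Michaelis-Menten rates with multiplicative
noise at eight log-spaced concentrations spanning 0.25–16×Km. All
generators are byte-deterministic under their seed and emit ground truth
alongside the data.

# Numerical choices and tolerances

* Kabsch degeneracy: second singular value below 1e-8 of the first is
  treated as collinear. Proper rotations are enforced to det +1 within
  1e-8.
* Axis extraction near 180° switches to the symmetric-part formula to
  avoid the sine-denominator blow-up.
* Guinier `qmax·Rg` limit 1.3; window iteration also terminates on a
  two-cycle to guard against oscillating membership.
* Mixture weights below the non-negativity boundary are handled by the
  active-set non-negative solver itself, never by clipping after an
  unconstrained fit.
* Levenberg-Marquardt runs with `ftol = ptol = 1e-14` so that exact
  synthetic data are recovered to ~1e-9 relative and rate-rescaling
  equivariance holds at that level.
* The Debye kernel treats `q = 0` and coincident points by the
  `sinc → 1` limit explicitly.

Two verification-oracle calibrations are worth stating. First, the solid
sphere check: a 5000-point uniform sample's Debye curve matches the
analytic sphere form factor to 5.7e-4 in normalised units across
`qR ≤ 4`, and to 0.2% point-wise relative up to `qR = 3`; point-wise
*relative* agreement near the form-factor minimum at `qR ≈ 4.49` is not a
meaningful claim at this point count, so the tests assert the normalised
absolute band there instead. Second, two-state recovery at 1% noise is
asserted on the Monte-Carlo estimate over 100 seeded replicates (bias and
typical error both within ±0.02; per-replicate sd ≈ 0.014 at the
generator's open/closed contrast).

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at the sizes stated above: 431-residue decoys, 150-point scattering
curves with 100-replicate noise Monte-Carlo, 1000 random 200-residue
sequences for the scanner/oracle equivalence, and 200 replicate kinetics
fits. Numeric cross-checks against deposited crystallographic
coordinates are additionally wired into the acceptance tests and run
automatically whenever local copies of the relevant PDB entries are
placed under `tests/testthat/deposited/` (or a directory named by
`KINCONF_DEPOSITED_DIR`); they fail with a pointer to that convention
when the files are absent, since coordinates are never downloaded at test
time.

# Known limitations

* Hinge estimation presumes the caller's domain definition; it will
  silently average over any internal deformation within the declared
  rigid domains (real conformers show 0.26–0.51 Å of such internal
  variation).
* The uniform-form-factor Debye model is unsuitable for absolute-scale
  or high-q work, and computed basis curves share none of the systematic
  errors of experimental curves, so real-data mixture weights carry
  model error the synthetic tests cannot see.
* The motif engine is a pattern matcher, not a profile/HMM scorer: it
  cannot weigh position-specific substitutability beyond the hard
  mismatch count.
* `classify` with the default spacing window is calibrated to one
  reference architecture; distant family members with large insertions
  between the catalytic loop and helix alpha-12 would need a wider
  window.
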