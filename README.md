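# kinconf

Conformer, scattering, motif and kinetics analysis of two-lobed sugar
kinases — built around the characterisation of a family of actinobacterial
glucosamine (GlcN) kinases with the eukaryotic-protein-kinase fold, whose
catalytic cycle hinges (literally) on the opening and closure of an N-lobe
against a C-lobe.

The package is for structural biologists and enzymologists who have some
combination of: multiple crystallographic conformers of the same two-domain
protein, 1-D small-angle X-ray scattering (SAXS) curves, candidate family
sequences, and saturation-kinetics measurements — and who want the standard
chain of analyses from those inputs with full synthetic-data testability.

## What it computes

**Conformer geometry.** Given an ensemble of conformers, `kinconf` measures
openness as the distance between two reporter C-alpha atoms (defaults:
residues 15 and 416, one per lobe), orders states open → closed, builds
pairwise RMSD matrices with independent align/measure residue ranges
(Kabsch superposition), runs ensemble PCA (porcupine mode vectors,
per-member projections), and estimates the interlobe hinge as a two-stage
rigid-fit decomposition: align the fixed domain, then decompose the residual
rigid transform of the mobile domain into an axis, a rotation angle

> cos θ = (tr R − 1) / 2,

and a screw translation along the axis.

**Two-state SAXS.** Theoretical profiles from C-alpha coordinates by the
Debye formula, I(q) = Σᵢⱼ fᵢfⱼ sin(q·rᵢⱼ)/(q·rᵢⱼ) with a uniform
per-residue form factor; automated Guinier analysis (iterated window with
q·Rg ≤ 1.3, Rg = √(−3·slope)); and the open/closed population estimate: a
σ-weighted non-negative least-squares fit of an experimental curve as
c_open·I_open(q) + c_closed·I_closed(q) + background, reported as volume
fractions w = c/(c_open + c_closed).

**Family fingerprint.** A PROSITE-style motif engine for the family
signature `Q-x(2)-RE-x(2)-YA-x(3)-LP-x-W` (helix α12, span 16) and the
catalytic-loop motif `D-x-H`, with mismatch-tolerant scanning and a family
call that requires both motifs at a start-to-start spacing of 60–160
residues (the reference enzyme's gap is 105; rule overridable).

**Kinetics.** Michaelis–Menten fits v = Vmax·S/(Km + S)
(Levenberg–Marquardt, data-driven starts, SE from the fit curvature, an
explicit flag when Km exceeds the sampled range) and reference-substrate
activity normalisation.

**Synthetic data.** Seeded generators with machine-readable ground truth
for every input class: hinge-rotated two-domain C-alpha decoys
(self-avoiding walks, 3.8 Å steps), noisy two-state scattering mixtures,
sequence sets with planted (optionally degraded) signatures, and noisy
saturation-kinetics tables.

## Worked example

A six-state synthetic ensemble generated at the experimentally observed
23.8° open/closed rotation, analysed end to end:

```r
library(kinconf)

sim <- make_hinge_ensemble(seed = 1)      # six conformers, 0-23.8 degrees
ens <- build_ensemble(sim$chains)
openness_table(ens, sim$truth$reporter_a, sim$truth$reporter_b)
#>                       member interlobe_A state
#> 1 synthetic_hinge_000.0deg:A    37.49420     I
#> 2 synthetic_hinge_004.8deg:B    36.65132    II
#> 3 synthetic_hinge_009.5deg:C    35.74659   III
#> 4 synthetic_hinge_014.3deg:D    34.78167    IV
#> 5 synthetic_hinge_019.0deg:E    33.75837     V
#> 6 synthetic_hinge_023.8deg:F    32.67859    VI

hinge_angle(ens$members[[1]], ens$members[[6]],
            fixed_range = sim$truth$fixed_resnos,
            mobile_range = sim$truth$mobile_resnos)
#> <hinge_result> 23.80 deg about (-0.000, -0.000, -1.000); screw -0.00 A

ensemble_pca(ens, align_range = sim$truth$fixed_resnos)
#> <ensemble_pca> 2 modes; PC1 99.6% of total variance
```

The openness column orders the states I (most open) to VI (most closed);
the hinge decomposition recovers the generating rotation and axis exactly,
and a single principal component carries essentially all ensemble variance,
as expected for a pure hinge motion.

```r
mx <- make_saxs_mixture(ens$members[[1]], ens$members[[6]],
                        w_open = 0.7, noise_cv = 0.01, seed = 1)
two_state_fit(mx$profile, mx$open_profile, mx$closed_profile)
#> <mixture_fit> open 69.9% / closed 30.1% (scale 1.002, bg -5.717, red. chi2 0.803)

guinier_fit(mx$open_profile)
#> <guinier_fit> Rg = 25.33 A, I(0) = 1.853e+05 (21 pts, q 0.005-0.05131, qmax*Rg = 1.30)

classify_glcnk(paste0(strrep("G", 299), "DGH", strrep("G", 102),
                      "QAAREAAYAAAALPAW"), seq_id = "demo")
#> <family_call> demo: GlcN kinase (signature at 405 with catalytic motif at 300 (gap 105 in [60, 160]))

mm_fit(make_kinetics_set(km_mM = 8, vmax = 100, cv = 0.05, seed = 1)$data)
#> <mm_fit> Km = 8.23 +/- 0.71 mM, Vmax = 102.1 +/- 2.4
```

A 70/30 open/closed mixture with 1% noise is recovered at 69.9%; the
family call fires because both motifs occur at the reference spacing; and
a 5%-noise kinetics table generated at Km = 8 mM fits back to
8.2 ± 0.7 mM.

## Command line

A thin wrapper over the same functions (subcommands `conformers`, `saxs`,
`motif-scan`, `kinetics`, `simulate`; global `--outdir`, `--seed`,
`--config`, `--log-level`; every run writes a `manifest.json` with input
parameters and output hashes):

```sh
Rscript inst/cli/kinconf.R simulate --kind hinge_ensemble --seed 5 --outdir sim/
Rscript inst/cli/kinconf.R conformers --structures sim/conformer_01.pdb,...,sim/conformer_06.pdb --outdir out/
```

(After installation the script also lives at
`system.file("cli", "kinconf.R", package = "kinconf")`.)

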