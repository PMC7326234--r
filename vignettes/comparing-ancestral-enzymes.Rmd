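---
title: "Comparing ancestral and modern enzymes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ancestral and modern enzymes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoenz)
```

`paleoenz` bundles the analyses that recur in ancestral-enzyme
resurrection studies: catalytic-promiscuity indices from steady-state
kinetics, two-state unfolding thermodynamics, crystallographic
flexibility comparison, substitution censuses, and active-site
volumetrics. This vignette explains the models behind each stage, the
parameters that matter, the numerical choices made, and what the
synthetic-data module does and does not emulate.

## Catalytic promiscuity from steady-state kinetics

Plate-reader assays yield absorbance slopes; `slope_to_rate` converts
them to molar rates by the blank-corrected Beer–Lambert relation
`rate = (slope − blank)/(ε·l)`. Sub-blank slopes are clamped to zero and
flagged rather than propagated as negative rates: a negative molar rate
is unphysical, and the flag preserves the audit trail.

`fit_michaelis_menten` fits `v = kcat·S/(KM + S)` by nonlinear least
squares in the v-vs-S form directly — no Lineweaver–Burk or other
linearization, which would distort the error structure. Starting values
are taken from the data (kcat from the maximum rate, KM from the
substrate concentration at half-maximal rate); `stats::nls` is tried
first with a bounded Levenberg–Marquardt fallback. The fit warns when the
substrate grid does not bracket the fitted KM and flags the
boundary-collapse case (rates flat in S, KM → 0) that saturated designs
produce.

The promiscuity index `P = (kcat/KM)_promiscuous / (kcat/KM)_primary` is
the reciprocal of the selectivity for the same reaction pair; the two
functions are kept separate because their arguments read in opposite
orders, and the identity `P × selectivity = 1` is enforced by a property
test. Published variant tables round P to one significant figure;
`build_promiscuity_table` reports both the rounded rendering and the full
value because the rounding is lossy (an efficiency ratio of 2.5e-4 prints
as 2e-4, and fold changes computed from printed values can differ from
those computed from full-precision values — both are reported, neither is
forced to agree with the other). Detection-limit efficiencies
("< 0.002") are modelled as bounds and propagate as inequalities, never
as point values.

## Two-state unfolding and the linear extrapolation method

The urea titration analysis is deliberately the classical two-stage
procedure rather than a global sigmoid fit:

1. `fraction_unfolded`: the native and unfolded plateau signals are the
   means inside explicit urea windows (with a fallback of the first and
   last 15% of the grid when no windows are given), and
   `f_U = (F − F_N)/(F_U − F_N)`, clipped to [0, 1] with flags.
2. `delta_g_points`: `ΔG = −RT ln(f_U/(1 − f_U))` with
   `R = 1.987e-3 kcal/(mol K)`, keeping only points with
   `ε ≤ f_U ≤ 1 − ε` (default ε = 0.05) because the log ratio diverges at
   the plateaus.
3. `fit_lem`: ordinary least squares of ΔG on [urea]; `m = |slope|`,
   `ΔG_H2O = intercept`, `c½ = ΔG_H2O/m`.

The default measurement temperature is 295.15 K (room temperature,
configurable). A positive fitted slope is rejected outright: it signals
data inconsistent with two-state denaturant unfolding.

**Plateau bias, quantified.** The two-stage estimator is exactly unbiased
only if the plateau windows contain pure native or pure unfolded protein.
For marginally stable proteins this is never quite true: with
`m·c½ ≈ 4.6 RT` (typical of the proteins this package targets), about 1%
of the protein is unfolded even at zero denaturant, so the native plateau
is contaminated and the band-edge ΔG points inherit the distortion. On a
noiseless curve with (m, c½) = (0.93, 2.9) and a 0–9.6 M grid the bias is
+2–3% in m; for a shallow unfolder (0.61, 3.8) on a 0–7.2 M grid — where
~3% of the protein is still folded at the top urea concentration — the
bias reaches ~14%, because the unfolded window then overlaps the
transition, violating the method's precondition. The package's recovery
studies therefore use a 0–9.6 M grid, a narrow native window
([0, 0.3] M), an unfolded window of [8.7, 9.6] M, and ε = 0.10; under
those conditions the noiseless bias is 1.8% (steep) and 4.0% (shallow),
and with 2% noise the median recovery error over 100 seeds stays within
5% in m and 0.1 M in c½. `fit_unfolding_global` fits the full sigmoid
(plateaus and thermodynamics simultaneously) and is free of the plateau
bias; it is provided as a cross-check, not the default, because the
two-stage route is what the field's published m-values mean.

**Comparing proteins.** When two proteins have similar m-values their
extrapolated ΔG_H2O values can be compared directly. When the m-values
differ, the unfolding processes differ and that comparison misleads;
`ddg_half_concentration` implements the recommended alternative
`ΔΔG = (c½_b − c½_a) × (m_a + m_b)/2`, positive when b is more stable.
The function computes the mean of the slopes from its inputs at full
precision; published tables sometimes quote a rounded mean, and the two
renderings can differ in the second decimal.

`fit_melting` fits a logistic transition between linear baselines.
Sloped baselines are the default (fluorescence baselines drift with
temperature); the transition guess comes from the steepest point of a
lightly smoothed derivative, and "no transition" is an error, detected
when the fitted amplitude is indistinguishable from the residual noise or
the midpoint leaves the scanned range.

## Flexibility from crystallographic B-factors

B-factors are standardized per chain over Cα atoms only:
`z = (B − mean)/SD`. The Z-scores have mean 0 and SD 1 by construction
(asserted to 1e-9), which makes chains from structures solved at
different resolutions comparable. `zscore_difference` subtracts aligned
Z-scores and reports contiguous runs with `|Δz| ≥ 1` (threshold
configurable) as flexibility-difference regions; alignment gaps are
excluded. Comparisons use chain A by default, matching the usual
deposited-structure convention.

## Alignment, superposition, substitutions

`align_chains` performs global (Needleman–Wunsch) alignment of the
Cα-derived sequences with BLOSUM62 and affine gaps via Biostrings;
identity is counted over aligned non-gap columns, and a C-terminal trim
rule excludes purification tags and linkers. `superpose` implements the
Kabsch SVD solution and returns the explicit rotation and translation (so
marked points, e.g. a tunnel start, can be transferred between frames
with `transfer_points`); it is cross-checked in the test suite against
`bio3d::fit.xyz` as an independent route.

Substitutions are classified conservative when their BLOSUM62 score is
positive. The criterion is a named, swappable policy (a custom function
can be supplied) because published conservative/non-conservative tallies
rarely state their criterion, and classifications of individual pairs
(e.g. Leu→Phe) are criterion-dependent. Surface exposure uses relative
per-residue SASA ≥ 1% — "at least some surface exposed" — with the
threshold configurable; the cap (lid) domain defaults to residues
108–179, the α/β-hydrolase convention for these enzymes. SASA itself is
computed by Shrake–Rupley sphere sampling on a deterministic Fibonacci
lattice (default 240 points per atom, probe 1.4 Å) against Bondi van der
Waals radii, with per-residue exposure normalized by Gly-X-Gly reference
areas. The deterministic lattice makes results reproducible without a
seed; the suite checks the isolated-atom closed form, the two-sphere lens
formula, and convergence under point doubling.

Interaction censuses are geometric and protonation-free: salt pairs are
oppositely charged atoms (Asp/Glu carboxylate oxygens negative; Lys NZ,
Arg guanidinium nitrogens, His ring nitrogens positive) within 7 Å;
hydrogen bonds are donor–acceptor heavy-atom pairs at 2.4–3.5 Å across
residues (explicit hydrogens are not required, as crystal structures at
typical resolution lack them); nonpolar contacts are inter-residue
carbon–carbon pairs within 4.5 Å. All criteria are echoed in the output,
because such counts are meaningless without them.

## Channel profiles and frustum volumetrics

The tunnel model is a clearance-radius profile: stations at fixed
arc-length steps (default 0.5 Å) along a user-supplied path, each with
the radius of the largest sphere centred there that touches no atom's van
der Waals surface. This inscribed-sphere definition is unambiguous and
testable; tools built on Voronoi searches define the local radius through
circumscribed constructions instead, so absolute volumes from such tools
are reference points rather than targets for this package. Automatic
tunnel discovery is out of scope by design — the path comes from the
user or from transferring a marked start point between superposed
structures.

Volumes are frustum sums, `π h (r₁² + r₁r₂ + r₂²)/3` between consecutive
stations, with linear radius interpolation for partial frustums at
segment bounds. The discretization converges at second order to
`∫π r(s)² ds`; the suite verifies additivity to 1e-9, monotonicity in the
radii, and agreement with a fine-step Riemann oracle and with the
synthetic tube's closed-form volume to 0.5%. Pinch points are local
radius minima whose depth below both flanking maxima exceeds a
prominence threshold (default 0.2 Å); monotone profiles have none. The
active-site segment is the innermost 10.5 Å of the profile, the
conventional first-pinch-point bound for this enzyme family, and the
cutoff is measured in arc-length along the tunnel, not Euclidean distance
from the start, because the volume integral runs along the path.

## The synthetic-data module

Each generator takes a `generator_spec(seed, noise_sd, grid)`; a fixed
seed gives bit-identical output and `noise_sd = 0` reproduces the
noiseless model to machine precision. Noise is additive Gaussian on the
measured signal — the plate-reader error model — which keeps recovery
tests interpretable.

- `gen_mm_rates`, `gen_unfolding`, `gen_melting` evaluate the exact
  models above on the supplied grid. Defaults mirror the bench
  conditions the package targets: ~750-unit fluorescence amplitude,
  room-temperature measurement, transitions a few degrees wide.
- `gen_tube_structure` builds a minimal single-chain alanine PDB whose
  carbon atoms lie on rings around the z axis, so the channel along the
  axis has a piecewise-linear clearance radius with an exactly computable
  frustum-sum volume. Two geometric corrections are required for the
  walls to realise the requested radii: on sloped sections the ring
  radius is inflated by `sqrt(1 + slope²)` (otherwise the inscribed
  sphere reads the obliquity-reduced cone distance, not the in-plane
  radius), and the wall is extended ~3 Å past both mouths along the end
  slopes (otherwise end stations see only the in-plane ring). Generation
  validates the realised clearance against the requested profile and
  refuses wall spacings too coarse to reproduce it within 5%.
- `gen_homolog_pair` plants substitutions that honour the same
  BLOSUM62-positive criterion used by the classifier (positions whose
  residue has no positive substitution partner — Cys, Gly, Pro — are
  re-drawn when a conservative substitution is required), and elevates
  hotspot B-factors by four baseline standard deviations so the
  planted regions are recovered exactly at the 1-SD differencing
  threshold even after per-chain renormalization.

What the generators do **not** emulate: realistic protein fold geometry
(homolog pairs are idealised helical Cα traces), crystallographic noise
models (B-factor noise is Gaussian, real B-factors are
resolution- and packing-dependent), correlated measurement error,
unfolding intermediates (curves are strictly two-state, while real
homologs of these enzymes can populate intermediates — one reason
measured m-values run below textbook values for 30 kDa proteins), and
ligands or waters in the tunnel. Passing recovery tests therefore
demonstrates the estimators are correct and well-conditioned under the
stated error model, not that real data meet that model.

## Pipeline and provenance

`validate_config` parses a YAML configuration with per-module sections,
collects *all* schema violations rather than failing at the first, and
fills defaults so the validated object is a complete record of the run.
`run_pipeline` executes the configured stages with per-stage fault
isolation (a corrupt input fails its stage, the others complete), writes
machine-readable CSV/JSON plus a run log recording the constants of
record (R, vdW radius set, SASA reference areas, census criteria), and
echoes the validated configuration verbatim; re-running from the echo
reproduces the machine-readable outputs byte for byte. Logging goes to
stderr and the log file; data go only to files, keeping the CLI wrapper
(`inst/cli/paleoenz.R`) pipe-safe.

## Problem sizes and limitations

The test suite and the acceptance script run entirely on synthetic data
at deliberate scales: 100-seed recovery studies for the urea fits,
25–35-point titration grids, 257-residue homolog pairs, tubes of a few
thousand wall atoms, and a few hundred randomized brute-force trials per
geometric primitive. Known limitations: the SASA implementation is
O(atoms × neighbours × points) R code, adequate for single chains but not
for large complexes; hydrogen-bond counting uses distance-only criteria
(no angles) and so over-counts relative to angle-aware definitions;
sequence alignment operates on Cα-derived sequences, so residues missing
Cα atoms are invisible to it; and the two-stage unfolding estimator
carries the plateau bias quantified above, which is why the global fit is
offered alongside it.
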