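# paleoenz

Quantitative comparison of resurrected ancestral enzymes with their modern
homologs.

When an ancestral enzyme is reconstructed and expressed, the questions that
follow are quantitative: is it more catalytically promiscuous than its
descendants, is it more stable, and do its structure and dynamics explain
the differences? `paleoenz` implements the analysis chain used to answer
those questions for α/β-hydrolase-fold enzymes such as hydroxynitrile
lyases (HNLs) and their esterase relatives, together with a synthetic-data
module so the entire pipeline can be exercised, tested and demonstrated
with no external downloads.

## What it computes

**Catalytic promiscuity.** For two reactions with catalytic efficiencies
kcat/KM, the selectivity is

    selectivity = (kcat/KM)_fast / (kcat/KM)_slow

and the promiscuity index is its reciprocal,

    P = (kcat/KM)_promiscuous / (kcat/KM)_primary ,

so P = 1 means both reactions are catalyzed equally well. Efficiencies come
from nonlinear Michaelis–Menten fits (`fit_michaelis_menten`) of rates
reduced from plate-reader absorbance slopes by the blank-corrected
Beer–Lambert relation (`slope_to_rate`). `build_promiscuity_table` lays out
a variant panel with fold changes and propagates censored (detection-limit)
efficiencies as inequalities.

**Unfolding thermodynamics.** Urea titrations are reduced in the standard
two-stage way: plateau windows give the fraction unfolded
(`fraction_unfolded`), points inside the usable band give
ΔG_unfold = −RT ln(U/N) (`delta_g_points`), and the linear extrapolation
method (`fit_lem`) returns the m-value, the half-unfolding concentration
c½, and ΔG_unfold,H₂O = m·c½. When two proteins have different m-values
their extrapolated ΔG values are not comparable; `ddg_half_concentration`
implements the recommended comparison ΔΔG = Δc½ × mean(m). Sigmoidal
melting-curve fits (`fit_melting`) and heat-challenge summaries
(`residual_activity`) complete the stability picture.

**Structural comparison.** Crystallographic B-factors of Cα atoms are
standardized per chain to Z-scores (`normalize_bfactors`), differenced
across aligned homologs, and flagged in contiguous flexibility regions
(`zscore_difference`). Global sequence alignment with identity
(`align_chains`), Kabsch superposition with RMSD (`superpose`),
substitution classification with surface exposure and cap/catalytic domain
assignment (`classify_substitutions`, `compute_sasa`), closest-atom
distances (`min_residue_distance`) and interaction/composition censuses
(`interaction_census`, `count_residue_types`) cover the structure-level
comparisons.

**Active-site volumetrics.** A channel through the protein is described by
a clearance-radius profile — the largest sphere centred on the path that
touches no atom's van der Waals surface (`clearance_radius`,
`trace_profile`). Its volume is the sum of right conical frustums,

    V = Σ π h (r₁² + r₁r₂ + r₂²) / 3 ,

with pinch-point detection and the conventional 10.5 Å active-site segment
(`profile_volume`, `find_pinch_points`, `active_site_volume`).

**Synthetic data.** `gen_mm_rates`, `gen_unfolding`, `gen_melting`,
`gen_tube_structure` and `gen_homolog_pair` generate every input type with
analytically known ground truth under a deterministic seed, including toy
PDB structures containing a tube of exactly computable volume and homolog
pairs with planted substitutions and flexibility hotspots.

## Worked example

```r
library(paleoenz)

# Promiscuity of an ancestral enzyme vs its modern descendant, from the
# measured efficiencies (1/(s mM)): primary = mandelonitrile cleavage,
# promiscuous = p-nitrophenyl acetate hydrolysis.
promiscuity(0.009, 17)     # ancestral enzyme
#> promiscuity P = 0.0005294 (reported 0.0005)
promiscuity(0.002, 8)      # modern homolog
#> promiscuity P = 0.00025 (reported 0.0002)
fold_change(0.0005294, 0.00025)$ratio
#> [1] 2.1176  -- the ancestor is about twice as promiscuous

# Stability comparison by the half-concentration method:
hb <- list(m = 0.93, c_half = 2.9, converged = TRUE)  # modern
h1 <- list(m = 0.61, c_half = 3.8, converged = TRUE)  # ancestral
ddg_half_concentration(hb, h1)
#> ddG = 0.693 kcal/mol (dc_half 0.90 M x mean m 0.770)

# Full synthetic round trip: generate a urea curve, recover the line.
cu <- gen_unfolding(0.93, 2.9,
                    spec = generator_spec(1, 0, grid = seq(0, 9.6, 0.3)))
fit_unfolding(cu, c(0, 0.3), c(8.7, 9.6), eps = 0.10)
#> two-state linear extrapolation fit:
#>   m      = 0.946 +/- 0.003 kcal/(mol M)
#>   c_half = 2.92 M
#>   dG_H2O = 2.767 +/- 0.010 kcal/mol
```

The recovered slope sits ~2% above the generating 0.93 because plateau
windows on a finite urea grid are never perfectly pure; the vignette
quantifies this bias and the conditions under which recovery is within 5%.

A complete multi-stage run (kinetics + stability + structures + tunnel)
is driven by a YAML configuration:

```r
report <- run_pipeline("config.yaml")
```

which writes per-stage CSV/JSON outputs, a run log, and an echo of the
validated configuration into the configured output directory.

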