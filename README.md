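# cdk2substrate

Tools for analysing how the cell-cycle kinase complex cyclin A/CDK2
recognises its substrates, built around the tumor suppressor p27^KIP1^ as
the model substrate. The package is aimed at structural bioinformaticians
and enzymologists who want a reproducible, scriptable version of four
desk-scale analyses that are usually scattered across web servers and
point-and-click tools:

1. **Consensus-motif statistics.** A curated table of 35
   in-vivo-confirmed human CDK2 phosphosites on 27 substrate proteins
   ships with the package. Each sequence window is anchored on its
   phosphoacceptor (P+0) and position-wise normalized amino-acid
   frequencies, sequence-logo information content
   (`IC = log2(20) − H(column)` bits) and motif statistics are computed
   for positions P−7..P+7. The headline statistics quantify the
   S/T-P-X-R/K/H consensus: the proline fraction at P+1 and the fraction
   of sites with a basic residue (R/K/H) at P+3.
2. **Peptide conformer model selection.** The protocol used for modelling
   disordered substrate peptides: generate a conformer ensemble, keep the
   models with ≥ 90 % of classifiable residues in favored Ramachandran
   regions, and select the model with the lowest backbone RMSD (Kabsch
   superposition over N, CA, C and shared O atoms) against a reference.
   Template choice is supported by ungapped sequence identity over the
   target length (`peptide_identity()`).
3. **Interface geometry.** Hydrogen bonds (donor–acceptor distance
   < 3.5 Å, hydrogen–donor–acceptor angle < 30°, with backbone amide
   hydrogens inferred geometrically), salt bridges (charged N/O pairs
   ≤ 4.0 Å, phosphate oxygens of ATP/phosphothreonine included), and
   ambiguous docking distance restraints (minimum heavy-atom inter-group
   distance against a ceiling) on kinase/cyclin/peptide complex models in
   PDB format.
4. **Michaelis–Menten kinetics.** Nonlinear least squares of
   `v = Vmax·S/(Km + S)` for substrate-velocity data, with standard
   errors, catalytic efficiency `Vmax/Km`, and wild-type vs mutant
   comparison with error propagation on the ratios.

A synthetic-data module generates every input with known ground truth:
peptide backbones from phi/psi internal coordinates (ideal geometry,
NeRF chaining), seeded conformer ensembles, complex fixtures with planted
contacts and decoys, and simulated velocity data with multiplicative
Gaussian noise.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` / `plot_*()` for figures.

## Worked example

```r
library(cdk2substrate)

# --- consensus statistics over the packaged phosphosite table
sites <- system.file("extdata", "cdk2_sites.tsv", package = "cdk2substrate") |>
  parse_site_table() |>
  anchor_sites()
motif_statistics(sites)
#> # A tibble: 1 × 5
#>   n_sites n_proteins frac_proline_p1 frac_basic_p3_sites frac_basic_p3_proteins
#>     <int>      <int>           <dbl>               <dbl>                  <dbl>
#> 1      35         27               1               0.829                  0.889
```

All 35 sites carry the invariant P+1 proline; 82.9 % of sites (and 88.9 %
of proteins) have a basic residue at P+3 — the S/T-P-X-R/K/H consensus.

```r
# --- model selection on a seeded 200-conformer ensemble
ens    <- sample_ensemble(n_models = 200, jitter_sd = 25, seed = 2024)
scores <- rama_filter(ens, threshold = 0.90)
sum(scores$passed_filter)
#> [1] 77
ref <- build_peptide("NAGSVEQTPKKPGLR", c(-120, 120), chain = "A", resno_start = 180)
select_model(ens[scores$passed_filter], ref)
#> # A tibble: 1 × 2
#>   model_id   rmsd
#>   <chr>     <dbl>
#> 1 model_027  1.25
```

77 of the 200 jittered conformers keep ≥ 90 % of residues in favored
Ramachandran regions; among those, `model_027` lies closest to the
extended reference (backbone RMSD 1.25 Å).

```r
# --- kinetics: wild-type vs R194A substrate peptide
wt  <- fit_michaelis_menten(
  simulate_velocities(Km = 93.6, Vmax = 2.21, cv = 0.05, seed = 42, peptide = "wt"))
mut <- fit_michaelis_menten(
  simulate_velocities(Km = 81.4, Vmax = 1.11, cv = 0.05, seed = 43, peptide = "R194A"))
wt
#> Michaelis-Menten fit [wt] (60 points)
#>   Km   = 95.91 +/- 3.95 uM
#>   Vmax = 2.22 +/- 0.0347 pmol/min
#>   Vmax/Km = 0.02315; RSS = 0.2153; converged: TRUE
compare_kinetics(wt, mut)
#> # A tibble: 1 × 8
#>   peptide_a peptide_b vmax_ratio vmax_ratio_se km_ratio km_ratio_se ...
#> 1 wt        R194A           2.03        0.0403     1.23      0.0662
```

The fitted maximal rate of the wild-type peptide is about twice that of
the R194A mutant (ratio 2.03 ± 0.04) while the Michaelis constants stay
similar — the P+7 arginine matters for turnover, not for apparent
affinity.

`run_pipeline()` chains all four stages from a flat key=value config and
writes per-stage TSV/JSON outputs plus a machine-readable
`summary.json`; see `?run_pipeline`.

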