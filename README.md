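# caspkit

Analysis toolkit for the rational redesign of protease subsite specificity,
built around the caspase-2 S1' promiscuity problem: a fusion-tag protease
should bind its recognition sequence (P5–P1) tightly but accept any amino
acid on the prime side of the scissile bond, because the P1' residue becomes
the new N-terminus of the liberated protein.

The package implements the full computational side of that redesign as
reusable, tested functions, with seeded synthetic generators standing in for
MD trajectories and wet-lab measurements:

- **Subsite promiscuity profiling.** Per-subsite amino-acid probability
  profiles from substrate tables (counts normalised by the background
  amino-acid frequencies of the human proteome) and the *cleavage entropy*

  `S_i = -Σ_a p_{a,i} · log20 p_{a,i}`

  with `S_i = 0` for a perfectly specific pocket and `S_i = 1` for a uniform
  distribution over the 20 amino acids.
- **Experimental cleavage entropies.** Measured relative times to 50%
  cleavage (Gly = 1) are translated to probabilities as `p ∝ 1/t50`,
  renormalised over the observed support, and pushed through the same
  entropy statistic, with Monte-Carlo uncertainty propagation from the
  replicate standard deviations.
- **Sequence/structure candidate selection.** Global Needleman–Wunsch
  alignment with affine gaps, percent identity under an explicit denominator
  convention, distance-based active-site stretch selection around the P1'
  residue of a structure, and nomination of prime-side differences as
  candidate mutations.
- **Thermodynamic-integration cycle analysis.** Per-λ ensemble averages of
  ∂H/∂λ with block-averaged standard errors, integration of the TI profile
  (`ΔG = ∫₀¹ ⟨∂H/∂λ⟩ dλ`, either directly or through a cubic spline
  evaluated on 101 λ points), dual-path cycle ledgers with totals, closure
  diagnostics, the catalytic split `ΔΔG‡ = ΔΔG_TI − ΔΔG_bind`, and
  replicate-scatter error combination.
- **Charging-correction bookkeeping.** Net-charge-changing perturbations
  carry ex-post correction terms (`ΔG_pol`, `ΔG_psum`, `ΔG_dir`, `ΔG_eps`);
  the ledger enforces `corrected = raw + Σ terms` and that charge-conserving
  steps carry no correction.
- **FRET Michaelis–Menten kinetics.** Fluorescence calibration, initial
  slopes, nonlinear least-squares fits of `v = Vmax·S/(KM+S)`,
  `kcat = Vmax/[E]`, catalytic efficiencies `kcat/KM`, and the conversion
  `exp(|ΔΔG|/RT)` from free-energy differences to rate factors.

Reference tables from the published caspase-2 redesign study (S1' substrate
distributions, the P1' cleavage-time scan, the dual-path free-energy
ledgers, and the fitted kinetic parameters) ship as plain-text fixtures
under `inst/extdata/`.

## Worked example

```r
library(caspkit)

# statistical promiscuity of the two S1' pockets
profs <- casp_p1prime_profiles()
round(cleavage_entropy(profs$casp2), 2)   # 0.56  (15 observed amino acids)
round(cleavage_entropy(profs$casp3), 2)   # 0.84  (20 observed amino acids)

# experimental entropy of the unmutated protease from the t50 scan
tab <- casp2_cleavage_times("unmutated")
entropy_uncertainty(tab, n_draws = 10000, seed = 20260924)
#> experimental cleavage entropy: 0.5000 (MC 0.5068 +/- 0.0145, 10000 draws)

# dual-path free-energy cycle of the quadruple mutant
l <- ti_reference_ledgers()
cycle_total(l$path1)                       # total 2.1, sd 4.85 kJ/mol
cycle_closure(l$path1, l$path2)            # 0.6 kJ/mol (below kT)

# kinetics: catalytic efficiency and the implied rate factor
catalytic_constants(kinetics_fit(KM = 89, kcat = 7.1e-3))
#>       kcat efficiency
#>    0.00710   79.77528
ddg_to_rate_factor(7)                      # 16.8
```

The entropies say the caspase-2 S1' pocket is markedly more specific (0.56)
than caspase-3's (0.84); the two engineered mutants move the experimental
entropy from 0.50 to 0.56 and 0.58. The cycle closure of 0.6 kJ/mol says
the two alchemical paths to the quadruple mutant agree to well below
thermal noise, and the kinetics arithmetic reproduces the published
catalytic efficiencies from the fitted `K_M` and `k_cat`.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full pipeline
over the bundled reference tables and synthetic data, writing their tables
under `results/`:

```sh
Rscript analysis/01_subsite_entropy.R        # statistical S1' entropies
Rscript analysis/02_experimental_entropy.R   # t50 -> entropy with MC error
Rscript analysis/03_candidate_selection.R    # alignment + active-site demo
Rscript analysis/04_ti_cycles.R              # cycle totals, closure, ddG‡
Rscript analysis/05_kinetics.R               # efficiencies, round trip
```

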