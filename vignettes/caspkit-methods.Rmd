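---
title: "Methods: subsite promiscuity, free-energy cycles and cleavage kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subsite promiscuity, free-energy cycles and cleavage kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspkit)
```

caspkit analyses the computational side of a protease-engineering problem:
making the caspase-2 S1' subsite promiscuous enough to cleave fusion tags
from arbitrary N-termini, without losing the tight P5–P1 recognition that
makes the enzyme safe to use. This vignette is the package's own account of
the models it implements, the parameters that matter, and the choices made
where the underlying procedures were genuinely open.

## Cleavage entropy

The promiscuity of a subsite $i$ is summarised by the base-20 Shannon
entropy of its amino-acid probability distribution,

$$ S_i = -\sum_{a=1}^{20} p_{a,i} \,\log_{20} p_{a,i}, $$

so that $S_i = 0$ for a pocket accepting a single amino acid and $S_i = 1$
for complete indifference. Implementation notes:

- $\log_{20} p$ is computed as $\ln p / \ln 20$, and $0 \cdot \log 0$ is
  defined as 0 (the continuity limit). Both are forced by the stated limits
  of the statistic.
- Amino acids never observed at a subsite keep probability exactly zero —
  no pseudo-counts. Smoothing would systematically inflate the entropy of
  sparsely observed pockets; the caspase-2 S1' profile has only 15 observed
  amino acids and its entropy (0.56) is reproduced only without smoothing.
- Raw substrate counts are normalised by the *natural occurrence* of each
  amino acid before renormalisation ([`normalize_counts()`]): a pocket that
  binds leucine no more often than leucine occurs in the proteome is not
  selective for leucine. A pinned snapshot of human proteome-wide
  frequencies ships as package data (`human_aa_frequencies()`); callers can
  supply their own, and profiles that are already normalised (like the
  bundled reference tables) bypass this step.

## Experimental cleavage entropies

Cleavage assays report the time $t_{50}$ to cleave half the substrate,
normalised to the Gly substrate. To compare measured promiscuity with the
statistical profiles, times are translated to probabilities as

$$ p_a \propto 1 / t_{50,a}, $$

renormalised over the observed support. The rule treats relative cleavage
speed as a stand-in for relative preference; it is scale-invariant (the Gly
normalisation cancels), order-reversing in $t_{50}$, and it reproduces all
three published entropy values (0.50, 0.56, 0.58) from the published time
tables to two decimals — the package's core consistency check for this
module. Proline, whose cleavage was too slow to quantify, is excluded from
the support rather than imputed; imputation would require inventing a time
for an unmeasurable reaction, and exclusion is required to reproduce 0.50.

The published $\pm$ values on these entropies have no stated propagation
method, so the package does not claim to reproduce them. Instead
[`entropy_uncertainty()`] propagates the replicate standard deviations by
Monte Carlo: each draw resamples every $t_{50}$ from a normal distribution
truncated at zero and recomputes the entropy. Defaults: 10 000 draws, and a
mandatory explicit seed — there is no hidden global RNG state anywhere in
the package.

## Sequence and structure analysis

Candidate mutations come from comparing the engineered protease with a
template whose S1' pocket already has the desired promiscuity. The steps:

1. **Global alignment** (Needleman–Wunsch with affine gaps). The alignment
   itself is standard, so it is delegated to Biostrings; the test suite
   checks the scores against exhaustive enumeration of all global
   alignments on short sequences. Defaults are BLOSUM62 with gap open 10
   and extend 0.5 — the original analysis names the algorithm but not its
   parameters, so identity percentages should be read qualitatively
   (they can shift by a couple of points with the gap model).
2. **Percent identity** counts identical columns over *all* alignment
   columns, gaps included, for determinism; `percent_identity(r,
   "ungapped")` gives the other convention.
3. **Active-site selection**: residues whose minimum heavy-atom distance to
   the modelled P1' residue is at most 1 nm seed contiguous stretches of 35
   residues (centred on the seed, clamped to the chain, merged when they
   overlap). Hydrogens are ignored — crystal structures lack them.
   Selection is monotone in the cutoff, which the tests verify.
4. **Candidate nomination** reports prime-side stretch positions where the
   two sequences differ, proposing the template's residue. Which stretches
   contact the prime side is inherently a visual/structural judgement, so
   the classification is a user-supplied configuration rather than
   something the package pretends to infer.

The full-protein inputs (accession sequences, the crystal structure with a
modelled P1'–P4' extension) are not bundled; the analysis drivers exercise
this code path on synthetic structures whose geometry is constructed by
hand, which tests the logic with verifiable ground truth.

## Thermodynamic integration and the cycle ledgers

An alchemical mutation's free-energy change is
$\Delta G_{A\to B} = \int_0^1 \langle \partial H/\partial \lambda
\rangle_\lambda \, d\lambda$. The module starts from per-$\lambda$ time
series of $\partial H/\partial\lambda$ (running the MD itself is out of
scope) and proceeds:

- **Per-$\lambda$ averaging** with an optional equilibration discard
  (default 0: production windows are assumed pre-trimmed) and a standard
  error from block averaging with 10 contiguous blocks, robust to serial
  correlation.
- **Integration.** `trapezoid` integrates the simulated points directly.
  `spline-101` emulates the extended-TI workflow in which a handful of
  simulated $\lambda$ points (typically 11) are densified to 101: a cubic
  interpolating spline (Forsythe–Malcolm–Moler end conditions, exact for
  polynomial mean curves up to degree three) is evaluated on the 101-point
  grid and integrated with composite Simpson, which integrates the cubic
  interpolant exactly — so the quadrature adds no error beyond the fit.
  Because both the spline and the quadrature are linear in the nodal means,
  per-node quadrature weights are obtained by propagating unit vectors, and
  the uncertainty follows in quadrature. Recovery of known polynomial
  integrals from noisy synthetic series, within three propagated standard
  errors, is a standing property test.
- **Cycle bookkeeping.** Mutation effects are differences of legs,
  $\Delta\Delta G = \Delta G^{\text{complex}}_{\text{mut}} -
  \Delta G^{\text{apo}}_{\text{mut}}$; a path's total is the sum of its
  steps with quadrature-combined spread; and two paths that build the same
  endpoint mutant in opposite orders must agree — the *cycle closure* is
  the convergence diagnostic. On ledgers generated from per-state scalar
  free energies the closure is zero to machine precision (tested); on the
  bundled reference ledgers it is 0.6 kJ/mol, well below $kT \approx 2.5$
  kJ/mol. The catalytic split $\Delta\Delta G^{\ddagger} =
  \Delta\Delta G_{TI} - \Delta\Delta G_{\text{bind}}$ separates the
  covalent-intermediate stabilisation from noncovalent binding.
- **Replicate combination** reports the mean and $n-1$ sample standard
  deviation over all replicate-by-site estimates, the scatter convention
  for independent repeats (unlike everywhere else, not quadrature — the
  estimates are repeats of the same quantity, not independent error
  sources).

## Charging corrections

Perturbing a neutral group into a charged one under periodic boundary
conditions with truncated electrostatics biases the raw charging free
energy; the bias must be corrected ex post. The package implements the
*bookkeeping*, not the continuum-electrostatics solvers: corrections are
supplied per mutation as up to four terms ($\Delta G_{pol}$,
$\Delta G_{psum}$, $\Delta G_{dir}$, $\Delta G_{eps}$), the corrected value
is raw plus their sum, and validation rejects a nonzero correction on any
charge-conserving perturbation (for those, the artifacts cancel between the
legs of the cycle). The bundled correction table stores only per-mutation
totals, because the individual term magnitudes were never published; they
are folded into the polarization term with a comment saying so. A crude
Born self-energy estimator ([`estimate_born_correction()`]) exists for
exploratory use and flags its output `estimated`; it is a deliberately
simple analytical model, not a replacement for a solver-based correction.

## FRET kinetics

Initial rates come from progress curves via a fitted fluorescence
calibration line and an OLS slope over the initial window (default 180 s,
within the "few minutes of excellent linearity" regime of the assay;
configurable, and much longer windows would bend under substrate
depletion). The Michaelis–Menten fit is unweighted nonlinear least squares
(the original fit's weighting is unstated) with starting values
$V_{max} = \max v$, $K_M = \mathrm{median}\, S$, and 95% confidence
intervals from the linearized covariance at the optimum. $k_{cat} =
V_{max}/[E]$ and efficiency $k_{cat}/K_M$ (with $K_M$ in molar) follow.
Published efficiency cells that derive from unrounded fit parameters
cannot match the printed $(K_M, k_{cat})$ arithmetic exactly; the package
asserts the rows that do reproduce, to one unit in the last printed digit.
Signal quenching at high substrate concentrations — the reason the
published $K_M$ intervals are wide — is not modelled.

`ddg_to_rate_factor()` converts a free-energy difference to the implied
multiplicative change in $k_{cat}/K_M$, $\exp(|\Delta\Delta G|/RT)$ at
298.15 K: 7 kJ/mol corresponds to a factor of about 16.8. The observed
gains are smaller (about 3-fold for Ile), a gap expected because the
tetrahedral intermediate used in the calculations is a proxy for, not the
same as, the kinetically relevant transition state.

## Synthetic data: what it emulates and what it does not

Every input the pipeline consumes has a seeded generator with ground truth
attached to the output, so recovery tests never re-derive truth from the
sample:

- `gen_substrate_counts()`: per-subsite multinomial draws from known
  profiles (emulating substrate-database tables).
- `gen_cleavage_times()`: triplicate lognormal times (mean-preserving,
  coefficient of variation as the noise dial; default replicates 3, the
  assay's design), each replicate renormalised by its own Gly draw exactly
  as the assay normalises.
- `gen_dhdl()`: Gaussian fluctuations around a polynomial mean curve at 11
  equidistant $\lambda$ points (default 250 samples per point), with the
  analytic integral as truth. Real $\partial H/\partial\lambda$ series are
  serially correlated and can have $\lambda$-dependent variance and
  curvature beyond degree three; passing the recovery tests therefore
  demonstrates correctness of the quadrature and error propagation, not
  convergence behaviour on real MD output.
- `gen_progress_curves()`: substrate depletion integrated with fixed-step
  RK4 (step 1 s, platform-stable), mapped through the calibration line with
  additive Gaussian noise. FRET photophysics (inner-filter effects,
  quencher saturation) are deliberately absent — which is exactly the
  regime where the real assay deviates at high substrate concentration.

Problem sizes in the tests and drivers (50 integration replicates, 100
coverage seeds, $10^5$ substrates for the law-of-large-numbers check,
brute-force alignment up to length 8) were chosen as the smallest sizes at
which the statistical assertions are stable.

## Known limitations

- The time-to-probability rule $p \propto 1/t_{50}$ is a modelling choice;
  any monotone decreasing map would qualify conceptually, but this one is
  parameter-free and matches all published entropy values.
- The extended-TI densification is implemented as spline interpolation of
  the mean curve; the original reweighting-based predictor needs the raw
  trajectories and is out of scope.
- Identity percentages depend on alignment parameters that were never
  published; treat them as qualitative.
- Confidence intervals on $K_M$ and $V_{max}$ are linearized (Wald-type);
  profile-likelihood intervals would be asymmetric for poorly determined
  $K_M$.
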