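---
title: "Methods: contact, entropy and free-energy analysis for PAM recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact, entropy and free-energy analysis for PAM recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pamscope)
```

This vignette documents the model choices, parameters and numerical
decisions behind each analysis stage in `pamscope`. It states no empirical
result that the test suite does not itself compute.

## Scientific setting

Cas9 recognizes its PAM largely through two arginines whose guanidinium
groups read guanine bases in the major groove; engineered variants relax
this readout by trading direct base contacts for phosphate-backbone contacts
and by repositioning the REC3 and HNH domains. Quantifying that trade
requires several estimators that must agree on conventions (units,
error models, correlation corrections), which is why they live in a single
package and are validated against synthetic inputs with planted answers.

## Contacts

A contact between a side-chain group and a DNA moiety is declared per frame
only when **both** criteria hold:

* centre-of-mass distance below 0.6 nm (nucleobase partner) or 0.5 nm
  (phosphate partner), and
* pairwise interaction energy (Coulomb + Lennard-Jones) at or below
  −100 kJ/mol (base) or −350 kJ/mol (phosphate).

The dual criterion suppresses transient near-passes that carry no energetic
signature and energetic artefacts at larger separations. Candidate pairs are
prefiltered by requiring at least 5% of pooled frames inside the distance
cutoff, which keeps the energy evaluation affordable without biasing the
retained pairs (the prefilter is inclusive at the threshold).

Occupancies are Bernoulli frequencies. Because consecutive frames are
correlated, the error uses an effective sample size
`n_eff = n * dt / (2 * tau)`, capped at `n`, with the integrated
autocorrelation time `tau` estimated by Sokal's self-consistent windowing
(window constant 6). A constant series has `tau = 0` by convention; white
noise gives `tau = dt / 2`, reproducing the iid error. Replicates are
aggregated as the mean of per-replicate means with error
`SD(means) / sqrt(R)`, which is robust to inter-replicate drift that the
within-replicate estimate cannot see.

The synthetic oracle is a two-state Markov chain whose persistence maps to
`tau` in closed form: with `mu = (2 tau/dt − 1)/(2 tau/dt + 1)` the chain
has exactly the requested integrated autocorrelation time, and run lengths
are generated geometrically. Coverage of the 95% intervals is checked on a
grid of occupancies and persistence times; chain length scales with
persistence (`n = 2000 * max(tau/dt, 1)`) so every cell contains a
comparable number of independent events.

## Hydrogen bonds

The geometric criterion is donor–acceptor distance ≤ 3.5 Å and
hydrogen–donor–acceptor angle ≤ 30° with the vertex at the donor. Hydrogens
must be covalently bound to their donor; unbound hydrogens are an input
error, not a zero. Per-triplet frequencies are summed within chemical
categories (e.g. PAM bases vs. backbone), and the specificity index is
`SI = f_PAM / (f_nonPAM + 1e-6)`; the small floor keeps the index finite
when the non-PAM class is empty, and a flag marks the degenerate both-zero
case. A "share" mode reports `f_PAM / (f_PAM + f_nonPAM)` capped at 1.
Errors propagate to first order in both frequencies.

## Superposition, RMSD, RMSF and domain distances

Superposition uses the Kabsch SVD solution with the determinant correction
that forbids reflections; collinear point sets are rejected rather than
silently solved. Backbone RMSD matches atoms by identity
(chain, residue number, atom name over N, CA, C, O) and reports how many
atoms were dropped on each side, so partial models cannot silently shift the
answer. RMSF fits every frame to the mean structure (two passes) before
computing per-atom fluctuations.

Domain separations are centre-of-mass distance series; distributions from
two simulations are compared with a two-tailed Z statistic whose standard
errors can be widened by the integrated autocorrelation times of each
series. The test suite checks the Kabsch result against a brute-force
rotation search (Euler-angle grid plus simplex refinement) and the Z
statistic against its closed form.

## Quasi-harmonic entropy

The mass-weighted covariance of fitted coordinates is diagonalized; each
eigenvalue maps to a frequency `omega = sqrt(kB T / lambda)` and a quantum
harmonic-oscillator entropy via `x = hbar omega / kB T`:

S = R * sum over modes of [ x/(e^x − 1) − ln(1 − e^{−x}) ].

The Schlitter formula is available as the standard upper bound. After
trajectory fitting, exactly six rigid-body eigenvalues are expected below a
floor of 1e-8 nm² amu and are dropped; a count other than six triggers a
warning because it usually indicates an unfitted or degenerate ensemble.
The planted-covariance oracle therefore calls the estimator with
`fit = FALSE`: fitting would consume six soft modes of the planted spectrum
and the closed-form answer would no longer apply. At `x = 1` a single mode
contributes 8.6525 J/mol/K, a convenient closed-form anchor.

Coordinates are stored dimension-major (all x, then y, then z), so
mass weights repeat as `rep(sqrt(m), times = 3)`.

## Well-tempered metadynamics

The engine integrates Langevin dynamics with the BAOAB splitting on
analytic potentials. Hills of width `sigma` are deposited every `stride`
with height `omega * t_G * exp(−V(s) / (kB (gamma − 1) T))`; the
free-energy estimate is `F = −gamma/(gamma − 1) * V`, shifted to zero
minimum. Multiple walkers share a single bias and write one hill log
ordered by (time, walker), matching the PLUMED multiple-walker convention;
HILLS files are read and written in PLUMED format.

Numerical choices:

* the bias is cached on a one-dimensional grid for speed, refreshed per
  deposition;
* harmonic walls (`k = 3500 kJ/mol/nm²` at ±1.5 nm in the double-well
  setup) confine the walker to the region of interest — without walls the
  tempered bias pushes probability into the unbounded tails and the basin
  populations become ill-defined;
* quantitative readings use `average_fes`, which averages the FES over the
  final 60% of checkpointed deposition times (40 checkpoints). A single
  terminal snapshot of a well-tempered run still carries hill-sized ripples;
  tail averaging removes them at no extra simulation cost;
* `fes_convergence` compares cumulative-prefix reconstructions against the
  final surface, giving a monotone root-mean-square deviation trace that is
  the package's convergence diagnostic;
* a kinetic-energy blow-up check aborts integration with an explicit error
  instead of producing silent NaN landscapes.

The double-well oracle `analytic_double_well(a)` has barrier `a` at `s = 0`
and degenerate minima at ±1; the reference basin free-energy difference from
Boltzmann integration is exactly 0 by symmetry, which the reconstruction
must reproduce without knowing it.

## Alchemical free energies

`mbar_solve` implements the multistate Bennett acceptance ratio on reduced
potentials: self-consistent iteration to a stable neighbourhood, then Newton
steps, with log-sum-exp throughout and the first sampled state anchored at
`f = 0`. States with zero samples reduce exactly to exponential averaging,
which the tests verify to 1e-8. Uncertainties come from the standard
asymptotic covariance estimate via SVD. Adjacent-state overlap below 0.03
triggers a warning, but only between states that both carry samples.

`optimize_lambda_schedule` greedily damps windows toward uniform neighbour
acceptance and inserts midpoints until every neighbour pair reaches a
minimum Metropolis swap acceptance (default 0.10). Cycle ΔΔG combines two
legs with errors in quadrature. Per-residue energy decompositions discard a
fixed initial fraction (10%) and report five-block standard errors.

The harmonic oracle: scaling a harmonic stiffness from `k` to `2k` changes
the free energy by `(kBT/2) ln 2 ≈ 0.864 kJ/mol` at 300 K, independent of
the spring centre; shifting the centre alone changes nothing. Both facts,
plus 95% interval coverage over repeated seeds, anchor the MBAR pipeline.

## Problem sizes and tolerances

Sample sizes used in the oracles (e.g. 1e4 draws per λ state, 5e4 ensemble
frames, 600 000 metadynamics steps with two walkers) were chosen so that
the statistical error of each estimator sits comfortably inside the checked
tolerance, while the full suite still runs in minutes on one core. They are
the package's own verification choices, not physical claims.

## Limitations

* The metadynamics engine targets analytic low-dimensional toys; it is a
  reference implementation for validating estimators, not a replacement for
  an MD engine.
* Entropy estimates inherit the quasi-harmonic assumptions: Gaussian
  fluctuations about one basin and no anharmonic or multi-basin
  contributions.
* Contact and hydrogen-bond criteria are fixed conventions; results are
  only comparable across systems analysed with the same thresholds.
* The MBAR covariance is asymptotic; at very low overlap the warning, not
  the error bar, is the reliable signal.
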