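---
title: "Methods: free energies, cycles and coupled sites in neqpka"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free energies, cycles and coupled sites in neqpka}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqpka)
```

`neqpka` turns nonequilibrium alchemical work values into protein pKa
predictions with uncertainties. This vignette is the package's account of
the science it implements: the statistical model, the conventions that had
to be fixed, the numerical choices, what the synthetic generator does and
does not emulate, and the known limitations.

## Work values and sign conventions

One *leg* of the calculation is the deprotonation of a residue in a fixed
environment (protein or reference peptide). Fast driven switches of the
alchemical coordinate λ from 0 to 1 each dissipate work; the work of a
single transition is the thermodynamic integration integral of dH/dλ along
the traversal, computed here by the trapezoidal rule on whatever λ grid the
input provides (`integrate_dhdl()`). The trapezoid is exact for piecewise
linear integrands and makes no uniform-grid assumption; no higher-order
quadrature is attempted because per-transition output is noisy anyway.

All works are kJ/mol, temperatures Kelvin, with R = 0.0083144621
kJ/(mol·K). Kilocalorie input is converted only under an explicit flag —
unit guessing is a classic source of silent 4.184-fold errors.

The one convention everything else leans on: **reverse works are recorded
in their own direction**. With that bookkeeping the Crooks fluctuation
theorem reads P_F(W)/P_R(−W) = exp[β(W − ΔG)], and the dissipationless
limit is W_F = ΔG, W_R = −ΔG. Reverse dH/dλ curves therefore integrate
from λ = 1 down to 0, so the same integrand yields opposite-sign works in
the two directions.

## The BAR estimator

BAR is the maximum-likelihood estimate of ΔG given both work samples. We
implement it through the label likelihood: pooling all works in the forward
frame, a sample at work W is a forward draw with probability
[1 + (n_R/n_F) e^{−β(W−ΔG)}]⁻¹. The stationarity condition is

$$\sum_i \left[1 + e^{\beta(M + W_i^F - \Delta G)}\right]^{-1} =
  \sum_j \left[1 + e^{\beta(-M + W_j^R + \Delta G)}\right]^{-1},
  \qquad M = \beta^{-1}\ln(n_F/n_R).$$

The sign of M on the two sides is not a matter of taste. We pin it by two
properties any implementation must satisfy: the deterministic limit
(W_F = {c}, W_R = {−c} must give ΔG = c for *any* n_F, n_R) and duplication
invariance (copying every sample changes nothing). Only the form above —M
on the reverse side — passes both; it also makes the estimator exactly
antisymmetric under swapping the two work lists. `bar_loglikelihood()`
exposes the likelihood so the root can be cross-checked by direct
maximization, which the test suite does on small instances against a dense
grid.

Numerics: the residual is smooth and strictly increasing in ΔG, tending to
+n_F and −n_R at ±∞, so the root always exists and is bracketed by
±(max|W| + 50/β). We run safeguarded Newton (analytic derivative, bisection
fallback when a step leaves the bracket) to an absolute tolerance of 1e−8
kJ/mol (internally 1e−10). The bootstrap solves all resampled roots
simultaneously with a row-vectorized version of the same iteration,
verified against the scalar solver.

Degenerate inputs: empty work lists and non-finite works are errors. Poor
forward/reverse overlap is *not* an error — the estimate still exists — but
`bar_estimate()` warns when the histogram overlap coefficient
(`overlap_diagnostic()`) drops below 0.02, a level at which the Gaussian
pair's overlap corresponds to well over 10 kJ/mol of dissipation and BAR
estimates become practically unusable.

`jarzynski_estimate()` is deliberately secondary: the one-sided exponential
average is biased at finite n (high from the forward side, low from the
reverse side), which is itself useful — the two Jarzynski estimates bracket
BAR on healthy data, and the test suite checks that ordering on average.
A Crooks-Gaussian-intersection estimator is intentionally not provided.

## Uncertainties

Bootstrap SEs resample the forward and reverse lists **independently**,
each with replacement at its original size, and take the SD of the
re-estimated ΔG over replicates. Whether the two directions should be
resampled jointly is genuinely open; independent resampling matches their
physical independence (different trajectories) and is flagged here as the
package's choice. The default is 1000 replicates — enough that the SE of
the SE (~2%) is negligible against the factor-1.3 calibration the tests
enforce. Resampling is deterministic given `seed`.

Leg SEs propagate in quadrature through the cycle
(`ddg_from_legs()`), and the reference pKa° uncertainty is *included* by
default in prediction SEs; `include_ref_error = FALSE` reproduces the
common practice of propagating only the alchemical uncertainty.

## From ΔΔG to pKa

pKa = pKa° + s·ΔΔG/(RT ln 10), with s = +1 for ASP/GLU and −1 for LYS.
The sign lives inside the conversion so that worksets *always* describe
deprotonation; a single alchemical direction convention pipeline-wide
turned out to be much harder to get wrong than per-class work-sign
flipping. RT·ln 10 is computed from R and T (≈ 5.708 kJ/mol at 298.15 K),
never hard-coded. Reference values default to ASP 3.94 ± 0.03, GLU
4.25 ± 0.05, LYS 10.4 ± 0.08 and are overridable via
`residue_class_refs()`; temperature is a required input defaulting to
298.15 K, since experimental benchmark temperatures vary by system.

Consensus across force fields is the unweighted mean of pKa values with
SE = √(Σse²)/k. Averaging on the pKa scale versus the ΔΔG scale is
equivalent within a residue class up to the shared reference constant; we
average pKa as the primary rule and provide `consensus_ddg()` and an
inverse-variance-weighted variant for sensitivity checks.

Estimate *kinds* (`standard`, `intrinsic`, `conditional`) are first-class
metadata. An intrinsic pKa is computed with all neighboring titratable
residues clamped (a pH-independent environment); a conditional one records
the clamped neighbor state verbatim (e.g. `"HIS31 doubly protonated"`).
The benchmark layer refuses to pool mixed kinds unless told to — silent
averaging of conditioned and standard estimates is a realistic failure
mode in pKa meta-analysis.

## Coupled sites

For two interacting titratable sites we use a grand-canonical
four-microstate model: relative free energies G(HH) = 0, G(H−) = g_b,
G(−H) = g_a, G(−−) = g_a + g_b + w, with
g_x(pH) = RT ln 10 · (pK_x − pH), so deprotonation of a site is favorable
exactly above its intrinsic pKa, and w > 0 penalizes the doubly
deprotonated state (mutually repulsive anions). This is the minimal model
consistent with intrinsic pKas plus a pairwise interaction; with w = 0 each
marginal collapses *exactly* (to 1e−12 in the tests) onto the one-site
Henderson–Hasselbalch curve, which anchors the parameterization to the
single-site theory. Weights are normalized with a max-subtracted softmax,
so normalization is exact at any pH.

The apparent pKa of a site is the pH at which its protonated-fraction
marginal crosses 0.5 — the same reading NMR titrations use. The root is
refined on the exact marginal (not the grid interpolant) to 1e−8 pH when
the curve carries its dyad; a monotone Hyman spline is the fallback for
bare curves. A curve that never crosses 0.5 inside the grid is an error
asking for a wider grid, not an extrapolation.

Triads reduce to dyads by designating the site with the lowest intrinsic
pKa as deprotonating first; the remaining pair's intrinsic pKas shift by
their coupling to that fixed anion, w/(RT ln 10) each. An exact tie for
the most acidic site is an explicit error: the reduction is then ambiguous
and the user must break the tie. The interaction energy w is an input;
`dyad_w_from_ddg()` derives it from four conditional ΔΔG values (each site
with the partner clamped in each state) and warns when the thermodynamic
cycle closure is violated.

`hh_fit()` fits f(pH) = 1/(1+10^(pH−pKa)) by least squares over the single
parameter with `stats::optimize` on [min(pH)−10, max(pH)+10]; flat input
(all fractions equal) is an error since the data then carry no pKa
information.

## The synthetic generator

`gaussian_cft_pair()` draws forward works from N(ΔG + βσ²/2, σ²) and
reverse works from N(−ΔG + βσ²/2, σ²) — the unique Gaussian pair with a
common σ satisfying the Crooks relation exactly at the density level.
Mixtures of such pairs at a shared ΔG stay Crooks-consistent (the same
exponential factor multiplies every component) and provide non-Gaussian,
skew-capable stress tests. `cft_ratio_check()` verifies generated (or real)
data empirically: on shared histogram bins, ln[P̂_F(W)/P̂_R(−W)] regressed
on W must give slope β and intercept −βΔG; the fit is inverse-variance
weighted (delta-method bin variance 1/n_F + 1/n_R) because unweighted
log-count regression is visibly biased by sparse tail bins.

`synthetic_residue_dataset()` emulates the *design* of a residue benchmark:
class composition defaulting to proportions 57:48:39 (ASP:GLU:LYS), true
shifts from N(0, 1.5 pK) truncated to ±5 pK — shifts in folded proteins can
reach about that magnitude — 200 transitions per direction per leg by
default, and σ = 5 kJ/mol of work spread, a moderate-dissipation regime.
Peptide-leg baselines are arbitrary (uniform 20–60 kJ/mol) since the cycle
subtracts them. The truth table carries every latent value. A configurable
fraction of residues is marked as coupled pairs with recorded interaction
energies; their worksets still encode the intrinsic shift, leaving the
pH-dependent correction to the coupling module, which mirrors how coupled
sites are handled in practice (standard calculation first, dyad treatment
second).

What the generator does **not** emulate: force-field error, conformational
sampling error, slow environmental relaxation, anharmonic work-distribution
tails beyond what mixtures produce, and any correlation between transitions
launched from a common equilibrium trajectory. Passing tests therefore
demonstrate the *analysis* is unbiased and calibrated given work data that
obey the Crooks relation — not that MD-derived predictions reach this
accuracy. On real data the error budget is dominated by the terms above.

## Benchmark statistics

AUE is the mean |predicted − experimental|; Pearson r uses `stats::cor`
behind a guard that makes zero-variance input an explicit error. The guard
matters because the null model — predict pKa° for every residue, the
baseline any predictor must beat — has *no defined within-class
correlation*; its cross-class correlation (driven by the spread of the
reference values themselves) is computable and reported separately.

Bootstrap SEs for the metrics resample residues with replacement;
degenerate resamples are skipped and counted. The per-class breakdown
reports each class and an `overall` row whose AUE is the unweighted mean of
class AUEs (classes differ in size, and class-mean reporting is the
convention for this benchmark style); a residue-weighted overall is
available behind a flag. "Adjusted" records — residues whose standard
prediction is replaced by a coupling- or condition-aware one — are an
explicit user-supplied substitution (`apply_adjustments()`), marked with a
flag, never inferred, because selecting which residues to adjust is an
analysis decision that must stay visible.

`convergence_curve()` subsamples n transitions per direction without
replacement and reports the mean and SD of the BAR estimate versus n; at
full size every subsample is a permutation, so the SD is exactly zero —
a useful self-check of the machinery as well as of protocol convergence.

## Problem sizes and tolerances in the shipped checks

The test suite and `scripts/acceptance.R` run the estimator sweep at
ΔG ∈ {−20…20} × σ ∈ {1, 5, 10} kJ/mol with n = 1000/1000 and 100 replicates
per cell; bootstrap calibration uses 300 regenerations of 200/200-work
sets; the density-ratio check uses 1e5 samples per direction; the
end-to-end benchmark uses 100 residues at 200 transitions per direction per
leg. These sizes give each check comfortable statistical headroom (4-SE
containment, factor-1.3 SE calibration, ±5-point coverage) while keeping a
full run in the minutes range on one core. Key tolerances: BAR root 1e−8
kJ/mol; oracle agreement 1e−4 kJ/mol; dyad marginals 1e−10 against
enumeration; HH-limit 1e−12; apparent pKa 1e−5 pH.

## Known limitations

- Only ASP, GLU and LYS are supported as probed residues; histidine enters
  only as a clamped neighbor in conditional estimates (its tautomers would
  need a richer microstate model).
- Coupling handles dyads and triads-reduced-to-dyads; clusters of more than
  three sites and pH-dependent conformational ensembles are out of scope.
- The XVG reader covers the two-column dH/dλ dialect (with `#`/`@`
  comments and an optional time-as-λ mapping); energy and trajectory files
  are not parsed.
- Bootstrap SEs inherit the usual small-n caveats; below ~50 transitions
  per direction they can be noticeably optimistic, which the convergence
  curve makes visible.
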