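---
title: "Methods: CD melting analysis and four-state thermodynamics of Gdm-bound DNA origami"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CD melting analysis and four-state thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(origamimelt)
```

# The scientific problem

DNA origami triangles exposed to guanidinium (Gdm⁺) salts pass through
several structural states during thermal denaturation: the intact
nanostructure (S1), a Gdm⁺-bound "damaged" state (S2), a Gdm⁺-free
pre-melting intermediate (S2′, spelled `S2p` in code), and single-stranded
DNA (S3). Three complementary observables probe this system at different
scales: AFM images classify individual structures as intact or damaged;
CD spectra report base stacking and helix chirality; and the 260 nm
absorbance reports base-pair opening through the hyperchromic shift.
`origamimelt` turns these observables into state populations and
transition thermodynamics.

# Melting temperature from hyperchromicity

The ssDNA fraction is the A260 curve normalised between two fitted linear
baselines,

$$f(T) = \frac{A(T) - A_\mathrm{low}(T)}{A_\mathrm{high}(T) - A_\mathrm{low}(T)},$$

and $T_m$ is the temperature at $f = 1/2$, located by linear interpolation
between the two bracketing grid points. The midline ("median") of the two
baselines in absorbance space maps exactly to $f = 1/2$ after
normalisation, so the two readings of the construction coincide; this is
the implemented one. Numerical choices:

- Default baseline windows are the first three and last three grid
  temperatures; the windows are configurable, and a warning fires if the
  fitted slope inside a window exceeds 0.5 % of the absorbance span per
  degree Celsius, which indicates the window reaches into the transition.
- Fractions are clipped to $[0,1]$; the pre-clip values are kept in
  `$raw` for diagnostics, because noise legitimately overshoots the
  baselines.
- If the curve crosses 1/2 more than once (baseline noise), the upward
  crossing with the steepest local slope is used and a multi-crossing flag
  is set; a monotone sigmoid yields a unique, unflagged crossing.
- The normalisation is affine-invariant: rescaling the absorbance leaves
  $f$ and $T_m$ unchanged (a tested invariant).

# Temperature-sensitivity maps

The TS statistic is the least-squares slope of CD versus temperature over
each window of three consecutive measurement points, reported at the
window's central temperature in mdeg/K. Regression on the actual
temperatures handles the uneven acquisition grid naturally. A Pearson
correlation variant (`method = "pearson"`) is available for comparison;
the slope is the default because it is the first-derivative reading of
the windowed correlation. Windows touching any HT-masked point are
reported missing rather than zero, since 0 mdeg/K is a meaningful value.
Extrema are ranked by |TS| with a deterministic tie-break (lower
wavelength, then lower temperature), and a feature "coincides" with
$T_m$ when it lies within 2 K of it — about half the grid spacing near
the melting region.

# Four-state thermodynamic model

Each transition between states carries

$$\Delta G(T) = \left[\Delta H_0 + \Delta C_p (T - T_0)\right]
  - T \left[\Delta S_0 + \Delta C_p \ln(T/T_0)\right],$$

with all temperatures in Kelvin — $\ln(T/T_0)$ and $e^{-\Delta G/RT}$ are
only meaningful on an absolute scale, so Celsius appears exclusively at
the package boundary. $T_0$ is the reference temperature at which the two
states are equally populated; anchoring $\Delta S_0 = \Delta H_0 / T_0$
enforces $\Delta G(T_0) = 0$ exactly and removes the enthalpy–entropy
degeneracy from fitting. State populations are Boltzmann weights along
the topology S1→S2, S1→S2′, S2→S3 (S2′ is a dead-end branch from S1),
normalised by the partition sum and evaluated in log-space so that large
|ΔG| cannot overflow. Closure ($\sum_s p_s(T) = 1$) is asserted to
$10^{-12}$ on every curve.

The published parameter table for 4 M Gdm⁺ is shipped verbatim in
`reference_param_table()`. Its printed ΔS values are internally
inconsistent across transitions: the ratio ΔH/ΔS numerically equals the
printed $T_0$ on the *Celsius* scale for S1→S2 and S2→S3 but on the
*Kelvin* scale for S1→S2′. Since the original fitting script's
temperature convention cannot be reconstructed from the printed table,
`reference_params()` takes the printed $T_0$ (converted to Kelvin) as
primary and re-derives ΔS₀ as ΔH₀/T₀ — a documented package decision,
not a claim about the original procedure. The printed ΔS values are
retained in the table for consistency checks. ΔC_p values whose effect on
the original fit was marginal (bracketed in the source table) are flagged
`dCp_low_confidence`. The kJ units are read as kJ per mole of cooperative
unit.

`fit_thermo_model()` fits $(\Delta H_0, T_0, \Delta C_p)$ per transition
(ΔS₀ anchored) by Levenberg–Marquardt on the stacked population
residuals, with bounds (ΔH₀ ∈ [1, 5000] kJ/mol, $T_0$ within the data
range ± 30 K, ΔC_p ∈ [−200, 200] kJ/(mol K)) and a deterministic
multi-start: each transition's initial $T_0$ comes from the crossing
point of its two state-fraction curves, jittered by fixed offsets
(−10, 0, +10 K), giving 27 starts for three transitions. The best
solution by residual sum of squares wins. On noiseless model-generated
profiles the fit returns the generating parameters to machine precision;
with profile noise, the S1→S2′ branch is the weakest-identified piece
(its population never dominates), and its fitted $T_0$ can wander by
several K while the S1→S2 and S2→S3 temperatures stay within ~1–2 K —
the end-to-end test asserts exactly the well-identified pair.

# PCA and constrained ITTFA

The spectral matrix (wavelength × temperature) is decomposed by SVD
*without* mean-centering: the component spectra are physical objects in
data space, and centering would absorb one component into the mean.
Wavelengths containing any HT-masked point are dropped before the SVD so
the decomposition sees a complete matrix.

Rank selection takes the smallest $k$ whose residual standard deviation
after $k$ components is at most 1.5× the noise floor; the floor is the
known noise SD when supplied, otherwise the median of the trailing third
of the singular values divided by $\sqrt{\max(n_\lambda, n_T)}$ (the
Marchenko–Pastur-scale estimate of the noise singular-value plateau).
Data indistinguishable from pure noise return $k = 1$ with a
`no_structure` flag.

ITTFA then iterates target concentration profiles through the truncated
factor space: project onto the span of the leading right singular
vectors, clip to $[0,1]$, overwrite fixed profiles exactly (the ssDNA
fraction as S3), clamp anchored profiles into their band inside their
window, and rescale the free profile mass for closure at each
temperature. Unconstrained profiles start as needle targets at the
maxima of the leading factor scores (ties broken toward the lowest
temperature); anchored profiles start at their anchor inside the window
and at zero outside it — a constant extension of a high anchor would
coincide with the all-ones closure direction, which lies in the factor
space and traps the iteration. Convergence is a maximum profile change
below $10^{-6}$ within 500 iterations.

## Identifiability and the refinement stage

The projection loop alone cannot resolve the split between two
unconstrained states: any factor-space transfer between their profiles
that respects non-negativity and closure fits the data identically. This
is a property of the problem, not the algorithm — which is why the
analysis anchors *both* AFM observables: the intact fraction on S1 and
the damaged fraction on S2 (inside the 23–45 °C imaging window, where S2′
and S3 are barely populated and "damaged" ≈ S2). With anchors at four
grid temperatures in a four-dimensional factor space, the transfer mode
is pinned. S2′ itself carries no constraint; it is the closure remainder.

A refinement stage then alternates least-squares spectra with
constrained non-negative least-squares profiles (closure as a penalty
row), where anchors enter as weighted soft targets
(`anchor_weight = 10`): among equally well-fitting solutions, the one
closest to the anchor centres is selected. A weak ridge (weight 0.3)
toward the current iterate damps motion along directions the data leave
flat, and the stage stops at a movement below $10^{-5}$ or after 400
rounds — where anchors do not reach, the flat directions are ill-posed
and early stopping regularises them. Degenerate solves (collinear
spectra during iteration) fall back to the previous iterate.

Under the sulfate reference thermodynamics the S2/S2′ split above 45 °C
remains genuinely ambiguous from that dataset alone (the alternative
splits are themselves nearly model-conform). `cross_dataset_refine()`
addresses this the way the two-salt experiment was originally analysed:
one dataset's component spectra serve as the first guess for the other
(`seed_profiles`), homologous spectra are averaged, and each dataset's
profiles are re-fitted against the shared basis until the inter-dataset
spectral distance stops decreasing (the trace is non-increasing by
construction). Seeding the ambiguous dataset from the well-resolved one
recovers both in the tested two-salt scenario.

# The synthetic-data generator

`generator_config()` encodes the study conditions: the 16-temperature
heat ramp (20–90 °C), wavelengths 200–330 nm at 1 nm pitch, Gaussian CD
noise of 0.05 mdeg SD per point (replicate CD variance is not reported
anywhere; 0.05 mdeg is a realistic photometric noise for a few-mdeg
signal and keeps tests analytic), A260 noise of 0.002 OD, linear A260
baselines at 1.0 and 1.3 relative OD with zero slope, an HT failure
cutoff at 205 nm modelled as a hard threshold (real detectors fail
gradually; the analysis applies a single 600 V criterion, so a hard
cutoff is the matching idealisation), and binomial AFM counts of 450
structures per image, three images per condition, at the four incubation
temperatures 23/30/37/42 °C. Scenario presets use the reference
thermodynamics for chloride and sulfate; the `no_gdm` control has three
states (S1, S2′, S3) with ΔC_p = 0 transitions placed so the global melt
sits near 63.9 °C — the three-state picture that suffices without Gdm⁺.

Component spectra are sums of Gaussian lobes per state: each state has a
deep-UV lobe plus the canonical negative (~247 nm) / positive
(~260–280 nm) near-UV pair, with centres and widths varied per state so
the four spectra are linearly independent — the states must be
spectroscopically resolvable for a four-component analysis to be the
right model, as it is in the system being emulated (S2's positive lobe
is reduced and red-shifted to 266 nm, S2′ is broadened, S3 is globally
weak). What the generator does *not* emulate: correlated (wavelength-
dependent) instrument noise, baseline drift between scans, gradual HT
degradation, AFM classification ambiguity (counts are exactly binomial
in p(S1)), and any kinetic lag between incubation and measurement.
Passing recovery tests on this generator therefore demonstrates the
correctness and identifiability of the analysis chain under the stated
statistical model, not robustness to instrument systematics.

# Problem sizes and determinism

The test suite runs the full chain on 131 × 16 spectral matrices, 20
seeds for the stochastic recovery studies, and 27-start thermodynamic
fits — sizes chosen so the complete suite runs in a few minutes while
keeping Monte-Carlo standard errors well inside the asserted margins.
All randomness flows through explicit seeds; equal seeds give
bit-identical datasets, exports and pipeline outputs.

# Known limitations

- The S2/S2′ decomposition above the AFM window is identified only
  through the soft-anchor selection rule (single dataset) or a shared
  spectral basis (two datasets); it has no finite-sample uncertainty
  estimate. Rotational-ambiguity band computation is out of scope.
- The S1→S2′ transition's parameters are weakly identified from noisy
  profiles; interpret its fitted ΔH₀ and ΔC_p with care and prefer the
  reference values when only one noisy dataset is available.
- Closure is enforced at all temperatures, including above $T_m$ where
  the notion of a total native-DNA concentration is a convention; the
  constraint step is isolated in one routine should a cutoff variant be
  needed.
- The TS statistic is the windowed slope (with a Pearson variant); full
  synchronous/asynchronous two-dimensional correlation maps are not
  implemented.
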