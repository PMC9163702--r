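# origamimelt

Thermal denaturation analysis of guanidinium-bound DNA origami from
circular dichroism (CD) melting data.

DNA origami nanostructures (here: the classic triangle folded from the
M13mp18 scaffold) denature in guanidinium (Gdm⁺) salt solutions in a
surprisingly anion-specific way: sulfate stabilises, chloride destabilises,
and structural damage appears well below the global melting temperature.
This package implements the analysis chain used to dissect that behaviour
for researchers working on nucleic-acid nanostructure stability:

- **I/O and screening** — CD spectral series (mdeg, wavelength ×
  temperature) with photomultiplier high-tension (HT) voltage screening at
  the conventional 600 V threshold; A260 melting curves; AFM
  intact/damaged count tables aggregated as mean ± SD of per-image
  fractions.
- **Melting temperature** — the ssDNA fraction is the A260 hyperchromic
  shift normalised between a lower and an upper linear baseline,
  f(T) = (A(T) − A_low(T)) / (A_high(T) − A_low(T)), and T_m is the
  temperature where f crosses 1/2, interpolated linearly between the two
  bracketing grid points.
- **Temperature-sensitivity (TS) maps** — the least-squares slope of CD
  versus temperature over sliding windows of three consecutive measurement
  points (mdeg/K, effectively ∂CD/∂T), with extrema location and a
  coupled/dephased classification against T_m.
- **Constrained ITTFA** — iterative target transformation factor analysis
  of the uncentered spectral matrix, decomposing the series into
  structural-state component spectra and concentration profiles under
  closure and non-negativity, with the ssDNA fraction fixed as the S3
  profile and the AFM intact/damaged fractions anchoring S1/S2 in the
  23–45 °C imaging window.
- **Four-state thermodynamics** — states S1 (intact), S2 (Gdm⁺-bound
  "damaged"), S2′ (Gdm⁺-free pre-melting intermediate; written `S2p` in
  code) and S3 (ssDNA), connected S1→S2, S1→S2′, S2→S3. Each transition
  carries a heat-capacity-aware free enthalpy

      ΔG(T) = [ΔH₀ + ΔC_p (T − T₀)] − T [ΔS₀ + ΔC_p ln(T/T₀)]

  with T in Kelvin and T₀ the equal-population temperature (ΔS₀ anchored as
  ΔH₀/T₀). Populations are Boltzmann weights along the topology, evaluated
  in log-space; `fit_thermo_model()` recovers (ΔH₀, T₀, ΔC_p) per
  transition from concentration profiles by multi-start
  Levenberg–Marquardt. A nonzero ΔC_p makes ΔG(T) non-monotonic, which is
  what reproduces the counter-intuitive rise-then-decline of intact origami
  between 20 and 45 °C in 4 M GdmCl.
- **Synthetic data** — a seeded generator emulating the experimental
  design (330→200 nm at 1 nm pitch, the 16-temperature heat ramp, Gaussian
  CD noise, sigmoidal A260, binomial AFM counts of a few hundred structures
  per image) with full ground truth, so every stage is testable without
  instrument data.

Reference transition parameters for 4 M Gdm⁺ with either anion ship as
`reference_param_table()` / `reference_params()`.

## Worked example

```r
library(origamimelt)
cfg <- pipeline_config(generator = generator_config("gdm_chloride"), seed = 1)
res <- run_full_analysis(cfg, out_dir = "out")
```

prints

```
simulated dataset (gdm_chloride scenario, seed 1)
HT mask at 600 V: 80/2096 points masked out
global Tm = 59.38 C
TS max |slope| = 0.415 at 245 nm / 60 C (coincides with Tm: TRUE)
eigenvalue analysis recommends rank 4; using k = 4
ITTFA: 4 states, lack of fit 5.57%, residual RMS 0.0757 mdeg
thermodynamic fit: residual RMS 0.015, converged TRUE
```

Reading the output: the HT mask drops the deep-UV wavelengths where the
detector saturates; the global T_m of 59.4 °C comes from the normalised
A260 curve; the strongest temperature sensitivity sits at 245 nm (the
negative CD lobe losing intensity) and coincides with T_m, i.e. base
unstacking and base-pair opening are coupled here; the eigenvalue analysis
finds four independent spectral components, and the AFM-anchored
decomposition plus thermodynamic fit return per-transition ΔH₀, ΔS₀, ΔC_p
and T₀ (in `res$fit$params`). The S1→S2 and S2→S3 transition temperatures
are recovered to within ~1 K of the generator truth at this noise level;
the S1→S2′ branch is only weakly constrained by noisy profiles (see the
methods vignette).

A thin command-line wrapper is included at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --scenario gdm_chloride --seed 1 --out out/
```

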