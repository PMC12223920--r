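# c2quant

Position-specific substitution analysis of hydrophilic cellulose ethers
(EHEC, MEHEC) from DNP-enhanced solid-state ¹³C NMR.

Cellulose ethers are modified at the C2, C3 and C6 positions of the
anhydroglucose unit, and the substitution pattern — not just the total
degree of substitution — governs their resistance to enzymatic degradation.
The 70–90 ppm region of a 1D ¹³C CP/MAS spectrum is too congested to read
C2 substitution directly, but a selective 1D J-coupling transfer experiment
can: the resolved C1 resonance (~103 ppm) is selected with shaped pulses and
a z-filter, its polarization is transferred to C2 through the one-bond
coupling by a perfect echo (τ–π–τ–π/2–τ–π–τ), and a control experiment
without the π/2 transfer pulse is subtracted to remove shaped-pulse
artifacts. In the difference spectrum, the signal at 90.1–80.4 ppm is
substituted C2 and at 80.4–71.9 ppm free C2, so

    % C2 substituted = 100 · I_sub / (I_sub + I_free)

with I the windowed integrals. Dynamic nuclear polarization (ε_DNP ≈ 120 in
these readily swelling polymers) makes the experiment feasible in hours at
natural ¹³C abundance.

The package implements the full computational methodology:

* **`spinsim`** — a product-operator simulator of the selective transfer
  experiment (perfect-echo, control, and double-quantum-filtered variants)
  with the 8-step phase cycle, z-filter, shaped-pulse attenuation/leakage
  and T₂′ losses, plus a Bloch integrator for truncated-Gaussian pulse
  excitation profiles. Validated against an independent dense density-matrix
  propagator to 1e-10.
* **`quantify`** — phasing, anchored fifth-order polynomial baseline
  correction, 1:1 per-scan control subtraction, boundary-exact window
  integration, and three uncertainty estimators (replicates, noise
  Monte-Carlo, baseline-anchor perturbation).
* **`relaxation`** — mono/stretched-exponential saturation-recovery fitting
  and a core–shell particle model showing that equal microwave-off buildup
  times of polymer and radical solution imply near-complete swelling
  (the apparent buildup time equals the shell value within 5% only for
  swelled volume fractions above 0.95).
* **`spectra_io`** — Bruker TopSpin processed-1D reader (ppm axis
  reconstructed from `procs`; integer and double data, both byte orders) and
  a plain two-column text interchange format.
* **`synthetic_data`** — seeded generators for spectra (peaks, spinning
  sidebands, baseline drift, calibrated noise) and transfer/control pairs
  with complete ground-truth records.
* **Command layer** — `cmd_quantify()`, `cmd_simulate()`, `cmd_relax()`,
  `cmd_synth()` driven by YAML configurations, each emitting JSON/CSV
  results and a provenance file that reproduces the run bit-for-bit; a thin
  Rscript wrapper lives in `inst/cli/c2quant.R`.

## Worked example

```r
library(c2quant)

# a synthetic transfer/control pair with known truth: 59% substituted C2,
# SNR 20, a z-filter artifact at 20% of the C2 area
pair <- make_transfer_pair(p_substituted = 0.59, snr = 20,
                           artifact_amp = 0.2, seed = 42)
quantify_c2(pair$transfer, pair$control)
#> <quant_result> % C2 substituted (90.1-80.4 ppm): 59.7
#>   integrals: substituted 5.86637, free 3.95823

# the pulse sequence it emulates: at J = 46 Hz and tau = 4 ms the perfect
# echo transfers sin^2(2 pi J tau) = 0.838 of the C1 polarization to C2
run_transfer_experiment(spin_system(J_IS = 46), tau = 4e-3)
#> <sequence_result> perfect_echo, tau = 4 ms, J = 46 Hz, 8 steps
#>   cycled I: 0.162334+9.1e-17i   cycled S: 0.837666+3.2e-16i   transfer steps: 8/8

# swelling check: an 18%-swelled shell does NOT explain equal microwave-off
# buildup times (apparent T = 11.4 s, far from the 3.3 s radical solution)
apparent_buildup_time(swelling_model(39.1, shell_thickness_for_fraction(0.18),
                                     microwaves_on = FALSE))
#> <recovery_fit> A = 0.8666, T = 11.38 s, beta = 1 (fixed), |resid| = 0.0264

boltzmann_gain(120, 0.6)   # depolarization-corrected DNP gain
#> [1] 48
```

The first number is the quantity of interest: the estimated percentage of
substituted C2 positions (truth here: 59). The sequence result shows the
per-scan transfer amplitude the simulator predicts, and the recovery fit
shows why the microwave-off buildup time discriminates surface wetting from
full swelling.

See `vignettes/c2-substitution-methods.Rmd` for the models, parameter
choices and limitations.

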