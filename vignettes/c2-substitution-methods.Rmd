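---
title: "Measuring C2 substitution in cellulose ethers by DNP-enhanced NMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring C2 substitution in cellulose ethers by DNP-enhanced NMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c2quant)
```

## The problem

Hydrophilic cellulose ethers (EHEC, MEHEC) are cellulose chains whose
anhydroglucose units (AGU) carry methyl/ethyl and hydroxyethyl substituents.
Which ring positions are substituted — especially C2 and C3 — matters for
biostability, but the 70–90 ppm region of a 1D ^13^C CP/MAS spectrum is too
congested to read position-specific substitution directly. Two ingredients
make it measurable:

1. **DNP sensitivity enhancement.** The ethers swell in a D~2~O/H~2~O radical
   solution, so microwave-driven polarization transfer boosts the ^13^C
   signal by two orders of magnitude and makes natural-abundance
   ^13^C–^13^C J-transfer experiments practical in hours.
2. **A selective 1D J-transfer experiment.** C1 is well resolved near
   103 ppm. Selecting C1 and transferring its polarization to C2 through the
   one-bond J coupling produces a spectrum whose 70–90 ppm signal comes from
   C2 only. Substituted C2 resonates around 84 ppm, free C2 around 75 ppm, so
   the ratio of the two integrals estimates the fraction of substituted C2.

`c2quant` implements every computational piece of that workflow: a two-spin
simulator of the pulse sequence, the quantification pipeline (phasing,
baseline, difference spectroscopy, integration), the relaxation models that
justify the DNP enhancement claims, and a synthetic-data generator that
provides ground truth for all of it.

## The two-spin simulator

The C1/C2 pair is modeled as two coupled spin-1/2 nuclei, I = C1 and S = C2.
The state is a vector of 16 coefficients over the Cartesian product-operator
basis \{E/2, I~x~, I~y~, I~z~, S~x~, S~y~, S~z~, 2I~a~S~b~\}. Evolution uses
the analytic product-operator rules: single-spin pulses act as 3×3 rotations
on each spin's operator index, and the weak-coupling Hamiltonian
2πJ I~z~S~z~ mixes the four fixed coefficient pairs (I~x~ ↔ 2I~y~S~z~, and
so on) through the angle πJt. The convention is right-handed,
ρ′ = U ρ U^†^ with U = exp(−iβI~φ~), so a 90°(x) pulse takes I~z~ to −I~y~.

The full experiment, per phase-cycle step, is

* nonselective CP, modeled as the boundary condition I~x~ + S~x~ (CP dynamics
  are sample physics and irrelevant to the ratio logic);
* a selective flip-back pulse on C1 (90° about −y), storing C1 along +z;
* a z-filter that destroys all remaining transverse coherence. The projector
  also zeroes the two-spin order 2I~z~S~z~ by default — the conservative
  choice, since CW dephasing does not protect it — with a flag to retain it;
* a selective flip-down on C1 whose phase steps through the 8-step cycle
  x,x,x,x,x̄,x̄,x̄,x̄ (receiver ȳ,ȳ,ȳ,ȳ,y,y,y,y), so anything created before
  the flip-down and not re-excited by it cancels over the cycle;
* the transfer block. For the **perfect echo**,
  τ–π(x)–τ–π/2(−y)–τ–π(x)–τ: an uncoupled C1 refocuses fully, while the
  coupled pair transfers with amplitude sin²(2πJτ) on S. The **control**
  omits the π/2, so its S channel carries only pulse artifacts — the ideal
  control S signal is exactly zero, which is what makes the difference
  spectrum a pure J-transfer measurement. The **DQ-filtered** variant places
  two π/2 pulses between the echoes.

Selective pulses carry two scalar imperfections, amplitude `attenuation` on
the target spin and `leakage` of the rotation onto the other spin. This
matches how shaped pulses behave at the level the analysis needs: the net
C1 retention across the z-filter is about 50% (so the per-pulse default is
√0.5), and the artifact excitation at the C2 offset is computed by
`shaped_pulse_profile()`, a Bloch-rotation integration of the truncated
Gaussian pulse (1 ms, 10% truncation by default). A full time-domain shaped
pulse inside the two-spin sequence would add nothing to the ratio logic.

### The DQ phase cycle

The published description of the DQ variant is a sketch, so the
implementation follows the standard coherence-order-selective rule: the
entire excitation block (flip-down, first echo π, first π/2) is shifted
through 0°, 90°, 180°, 270° (twice, for 8 steps) with receiver −2φ; the
reconversion π/2 is fixed at y. With the block conjugated by a total
z-rotation, any pathway that is not double-quantum during the filter period
cancels exactly over four steps; the surviving DQ term reconverts into
antiphase on *both* spins, which is why the per-scan transferred signal is
half the perfect-echo value, and why transfer occurs only in the φ ∈ {0°,
180°} steps — 4 of 8 scans. Single-spin residuals entering the block
transversely can still leak through a Δp = ±2 pathway, consistent with the
observation that this cycle handles DNP-scale artifacts poorly; that is
precisely the argument for preferring the perfect echo plus control
subtraction.

J and the echo delay τ are free parameters (defaults J = 46 Hz, a typical
glucose C1–C2 one-bond coupling, and τ = 4 ms). Detection is the complex
in-phase amplitude a~x~ + i·a~y~ per spin; lineshape rendering is done
separately by `spinsim_to_spectrum()`.

Every operation is cross-checked in the test suite against an independent
dense 4×4 complex density-matrix propagator (eigendecomposition matrix
exponentials) to 10^−10^ over randomized sequences; the two routes share no
code.

## Quantification pipeline

`quantify_c2()` runs the chain phase → baseline → subtract → integrate,
logging every step into a provenance record, because at these
signal-to-noise ratios the processing chain is the dominant subjective
element and should be auditable.

* **Phasing** rotates the complex spectrum by ph0 + ph1·(ppm−pivot)/span.
  Real-only input is accepted for zero-order phasing (the imaginary part is
  reconstructed by a discrete Hilbert transform); first-order phasing of
  real-only data is refused.
* **Baseline.** A fifth-order polynomial (order configurable) is fitted by
  least squares to anchor regions only — by default (190, 115) and (60, 10)
  ppm with the first spinning sidebands of C1 (at ±MAS rate expressed in
  ppm) excised — on an axis affinely scaled to [−1, 1] for conditioning. At
  least 2(order+1) anchor points are required; the operation is idempotent
  to numerical precision.
* **Difference spectroscopy.** The control is subtracted 1:1 after per-scan
  normalization (scan-count ratio); a least-squares scale over an
  artifact-only window exists but is off by default, because the reference
  procedure subtracts 1:1.
* **Integration.** Trapezoidal, over (high, low) ppm windows with the edge
  intensities interpolated, so integrals are exactly additive across the
  shared 80.4 ppm boundary and no point is double-counted. The default
  windows are 90.1–80.4 ppm (substituted C2) and 80.4–71.9 ppm (free C2),
  and the result is 100·I~sub~/(I~sub~+I~free~). Negative integrals (a
  low-SNR reality) are stored as-is with a warning and clamped to [0, 100]
  only in the summary view.

Uncertainty comes in three flavors: replicate standard deviation;
seeded Monte-Carlo noise propagation on the difference spectrum; and
anchor-region perturbation, which jitters the baseline anchors and measures
how much the answer moves. When only one sample has replicates, its
relative sd can be transferred to the others
(`transfer_relative_uncertainty()`).

## Relaxation models and the swelling argument

`fit_saturation_recovery()` fits A(1 − exp(−(t/T)^β)) by
Levenberg–Marquardt, with β fixed to 1 or free in [0.2, 1]. T is initialized
from the interpolated 1−1/e crossing, β at 1 (numerically 0.999, just inside
the bound, since LM cannot move a parameter started exactly on a bound);
bounds are T ∈ [10^−3^, 10^4^] s. Fits are invariant to amplitude scaling.

The core–shell model (`swelling_model()`) describes a particle of radius R
with a radical-wetted shell of thickness d: shell volume fraction
f = 1 − ((R−d)/R)³, buildup a(t) = w~shell~(1 − e^{−t/T~shell~}) +
w~core~(1 − e^{−t/T~core~}) with w~shell~ = f·ε (microwaves on) or
f·(1−depolarization) (off) and w~core~ = 1 − f. Defaults: T~shell~ = 3.3 s
(the radical solution), T~core~ = 13.3 s (dry powder at 100 K),
ε = 120, depolarization = 0.6 (the upper bound of the reported range, as a
config parameter). Spin diffusion between shell and core is neglected: with
D ≈ 10^−15^ m²/s and recycle delays under 10 s, `spin_diffusion_length()`
(defined as √(Dt), the convention that reproduces the ~0.1 µm figure) is
three orders of magnitude below the particle size.

The scientific point the model makes: with microwaves **on**, a thin
enhanced shell (f ≈ 0.18) already dominates the recovery curve, so an
apparent buildup time equal to the radical solution's proves nothing about
swelling depth. With microwaves **off** the shell is *not* enhanced, and the
apparent time approaches T~shell~ within 5% only when f > 0.95. Equal
microwave-off buildup on the polymer and on a dissolved reference therefore
implies near-complete swelling. `cmd_relax()` turns this into a verdict:
an on/off pair is "consistent with full swelling" only when both apparent
times match T~shell~ within tolerance.

## The synthetic-data generator

`make_transfer_pair()` emulates the measured transfer/control pairs with
known truth: C2~sub~ at 84 ppm and C2~free~ at 75 ppm in ratio p:(1−p), a
residual C1 at 103 ppm with 15% first sidebands, a broad pseudo-Voigt
z-filter artifact at 80 ppm present in both spectra, a fifth-order
polynomial drift, and seeded white Gaussian noise. Choices that matter:

* **Lineshape: Gaussian by default.** These ethers are highly amorphous, so
  the lines are inhomogeneously broadened — a Gaussian, not a Lorentzian,
  is the appropriate default. This also has a practical consequence:
  Lorentzian tails (missing area ∝ fwhm/(π·distance)) leak several percent
  across the 80.4 ppm boundary at 1.5 ppm width, which would bias any
  integration-window method; Gaussian tails are negligible there.
  Lorentzian and pseudo-Voigt shapes remain available per peak.
* **SNR definition.** The analysis needs a testable definition, so SNR is
  the larger noiseless C2 peak height divided by the per-point noise sd.
* **Determinism.** One RNG stream per fixture via `withr::with_seed()`; the
  seed is recorded in the truth record and the global RNG is untouched.
* **The artifact** is a broad (3 ppm) pseudo-Voigt: its true lineshape is
  unknown, only that it is broad, decayed and shared between transfer and
  control — which is all that matters, since the 1:1 subtraction removes
  whatever is shared.

What the generator does *not* emulate: t~1~ noise, lineshape differences
between transfer and control (e.g. differential T~2~′ weighting across the
C2 region), phase errors correlated with frequency, and non-polynomial
baseline pathologies. Passing the recovery tests therefore demonstrates that
the pipeline is correct and unbiased under the stated noise model — not
that real spectra cannot bias it; on measured data the
anchor-perturbation uncertainty is the relevant guard.

## Test problem sizes and stochastic protocols

Synthetic spectra use 8192 points over 240 ppm (typical of processed 1D
data). End-to-end recovery is checked on replicate means — 5 seeds per
condition at SNR 20 (±3-point band), 20 seeds at SNR 5 with a 20% artifact
(±5-point band) — sized so the Monte-Carlo standard error (≈0.7 points) is
well below the bands; a 100-seed study during development put the pipeline's
bias at −0.2 ± 0.3 points at SNR 5. The T-recovery property uses 32 delays
spanning 0.1–4 T, a standard recovery sampling; with 16 delays the
Cramér–Rao limit alone exceeds the 5% target. Oracle equivalence runs 100
randomized sequences. The swelling grid uses 21 fractions with noiseless
curves and 16 log-spaced delays over 0.1–3 T~core~.

## Worked example

```{r example, eval = FALSE}
pair <- make_transfer_pair(p_substituted = 0.59, snr = 20,
                           artifact_amp = 0.2, seed = 42)
res <- quantify_c2(pair$transfer, pair$control)
res
#> <quant_result> % C2 substituted (90.1-80.4 ppm): 59.7
#>   integrals: substituted 5.86637, free 3.95823
res$uncertainty_pct <- estimate_uncertainty(
  mode = "noise_propagation", diff_spec = subtract_control(
    fit_baseline(pair$transfer, baseline_spec(5, default_anchor_regions(pair$transfer)))$corrected,
    fit_baseline(pair$control, baseline_spec(5, default_anchor_regions(pair$control)))$corrected),
  noise_sigma = pair$truth$noise_sigma * sqrt(2), seed = 1)
```

## Known limitations

* The Bruker reader handles processed 1D real data only (`1r` + `procs`);
  FIDs, imaginary parts and other vendors are out of scope.
* The simulator is a two-spin model: no ^1^H reservoir, no MAS recoupling
  physics (the rotational-resonance matching of the CW field is a
  configuration note, not simulated), no multi-spin C2/C3 networks.
* Peak deconvolution of the C2 region (which would give C3 information) is
  deliberately not implemented.
* The percent-substitution estimator is a ratio of window integrals; it
  inherits any chemical-shift assignment error in the 80.4 ppm split point.
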