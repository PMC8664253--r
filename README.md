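# cryoblur

Quantitative models and analysis for **ultrarapid cryo-arrest microscopy**
— vitrifying living cells directly on a fluorescence microscope and
imaging the arrested molecular patterns.

At physiological temperature, Brownian motion during the finite time
needed to collect photons blurs every fluorescent structure: the effective
image variance is

> σ²_MB = σ²_PSF + 4 D Δt + r²,  D = k_B T / (6 π η r),

and substituting σ²_MB into the pixelated localization-variance formula

> v = (σ² + a²/12)/N + 16π (σ² + a²/12)² (b_m + b_v²) / (3 a² N²)

shows that localization precision and two-point resolution saturate with
photon number — more photons mean more time, which means more blur.
Cryo-arrest sets D = 0 and removes this limit. cryoblur provides, for
researchers developing or evaluating cryo-fluorescence methods:

* **`motional_blur_for()`, `localization_precision()`,
  `improvement_ratio()`** — the closed-form theory above;
* **`resolution_estimate()`** — Monte Carlo two-point resolution: photons
  drawn from two Gaussians of variance σ²_MB, binned to pixels, recovered
  with a Gaussian-mixture fit, resolved when the valley contrast
  C = 1 − I_min/I_max exceeds 1.7% in 95% of realizations;
* **`cooling_model()`** — the lumped one-sided cooling bound
  T(t) = ΔT(e^(−κAt/(cmL)) − 1) + T₀, giving the
  thermal-diffusivity-limited cooling rates of thin aqueous samples;
* **`flim_pipeline()`** and its stages (`register_stack()`,
  `estimate_background()`, `estimate_irf()`, `phasor_transform()`,
  `denoise_phasors()`, `fit_three_components()`,
  `molecular_fraction_maps()`) — phasor FLIM analysis of TCSPC stacks and
  three-component unmixing of a conformational FRET biosensor into
  donor-only / active / inactive states, yielding per-pixel molecular
  activity maps α;
* **`generate_tcspc_stack()`** — a synthetic TCSPC generator with ground
  truth (mixture decays, Poisson counts, IRF convolution, flat background,
  rigid drift) so the whole pipeline is testable without microscope data.

## Worked example

```r
library(cryoblur)

# How fast can a 13-um adherent-cell sample cool through its glass face?
m <- cooling_model(thickness = 13e-6)
m
#> One-sided lumped cooling model
#>   L = 13 um, A = 2e-05 m^2, kappa = 0.5562 W/m/K, c = 4 J/cm^3/K
#>   m = 0.26 mg, T0 = 37 C -> coolant -196 C (delta_T = 233 C)
#>   rate constant k = 822.8 /s; initial rate 1.917e+05 C/s
```

The initial rate, ~1.9 × 10⁵ °C/s, is the diffusivity-limited bound for a
13-µm water layer — fast enough to pass the ice-crystallization window
(0 to −130 °C) in about a millisecond.

```r
# Localization precision of a 100-nm structure emitting 1e5 photons,
# FWHM 100 nm PSF: warm (Brownian) vs arrested
improvement_ratio(100e-9, 1e5, fwhm_to_sigma(100e-9))
#> Localization-precision improvement by cryo-arrest
#>   rt  : 11.5 nm (N = 10000)
#>   cryo: 0.717 nm (N = 10000)
#>   fold: 16
```

At 37 °C the structure cannot be localized better than ~11 nm no matter
the optics; frozen, the same photon budget gives sub-nanometer precision.

```r
# Full FLIM round trip on a synthetic biosensor scene with known truth
gen <- generate_tcspc_stack(scene_preset("lifea2-cryo", seed = 7))
res <- flim_pipeline(gen$stack)
res
#> FLIM pipeline result
#>   drift-corrected frames: 2 (0 photons dropped)
#>   background: 0 photons/px (image and histogram estimates disagree)
#>   IRF: delay 0 ns, width 0 ns
#> Three-component phasor unmixing
#>   lifetimes (ns): donor-only 3.71, active 0.9, inactive 3.5 (fixed)
#>   donor-only photon fraction (fixed): 0.2
#>   pixels: 882; mean f_active = 0.175; RMS residual = 0.004059

lit <- gen$truth$lit & res$fit$mask
sqrt(mean((res$alpha[lit] - gen$truth$alpha[lit])^2))
#> [1] 0.04525557
```

`res$alpha` is the per-pixel molecular fraction of biosensor in the
active (high-FRET, 0.9 ns) conformation, renormalized to the sensing
population; the two planted activity levels (0.2 and 0.7) are recovered
with RMSE ≈ 0.045 at 1000 photons per pixel. (The background cross-check
note is expected on this zero-background scene: the histogram floor reads
the wrapped decay tail, the image-based estimate — correctly 0 — is
used.)

See `vignettes/cryoblur-methods.Rmd` for the models, parameter
conventions, numerical choices and limitations.

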