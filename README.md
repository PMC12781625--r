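# proteodyn

Quantitative analysis of proteasome mobility and assembly state from
fluorescence imaging, for cell biologists and microscopists studying
proteostasis. The package implements four analysis chains around a common
seeded simulator:

* **Single-particle tracking** — bandpass spot detection (1–5 px
  difference-of-Gaussians, 4σ threshold), sub-pixel 2-D Gaussian
  localization, greedy nearest-neighbour linking (≤ 6 px per 5 ms frame, no
  gap closing, tracks > 6 frames retained).
* **Jump-distance diffusion analysis** — the squared frame-to-frame
  displacement of a 2-D Brownian particle is exponential with mean 4DΔt, so
  a heterogeneous pool follows
  P(r², Δt) = Σⱼ fⱼ/(4DⱼΔt) · exp(−r²/(4DⱼΔt)).
  `jd_fit()` fits this mixture to the per-cell histogram of squared jumps
  (weighted least squares, Poisson weights) and selects m = 1 vs m = 2 by an
  R² > 0.9 gate on the single-population fit.
* **MSD motion classification** — per-track time-averaged MSD, the
  anomalous-diffusion fit MSD(τ) = Aτ^α + B, classification of α into
  free / confined / active / discarded (two threshold profiles), and the
  confinement-radius fit MSD(τ) = r_c²(1 − e^(−τ/b)) for caged particles.
* **Two-color SMLM stoichiometry** — second-order polynomial chromatic
  registration, cluster detection, one-to-one CP–RP pairing within 100 nm,
  unit-RP intensity from the distribution mode, and free / singly- /
  doubly-capped holoenzyme fractions on both the CP and RP side; plus
  nucleus/ER/cytosol compartment fractions against a label mask.
* **Voltage-response traces** — mono-exponential bleach correction, 10×
  temporal binning, zero-phase 0.05 Hz low-pass, normalization (nFI),
  prominence-based extrema detection (3%, ≥ 50 frames apart) and the
  per-cell intensity rate in nFI·s⁻¹.

Module-by-module background, parameter defaults with units, and the design
decisions behind the estimators are in the methods vignette
(`vignettes/proteodyn-methods.Rmd`).

## Worked example

Recover a fast/slow diffusion mixture and motion classes from simulated
tracks, a capping stoichiometry from a simulated two-color field, and a
voltage-response rate from a simulated trace:

```r
library(proteodyn)

## diffusion: two Brownian populations at the fast/slow regime
sp <- sim_spec(list(list(model = "brownian", D = 3.5, fraction = 0.5),
                    list(model = "brownian", D = 0.5, fraction = 0.5)),
               n_tracks = 2000, n_frames = 45, dt = 0.005, noise_sd = 0,
               seed = 42)
fit <- jd_fit(collect_jumps(simulate_tracks(sp)), m = "auto")
print(fit)
#> Jump-distance exponential-mixture fit (m = 2 )
#>   n jumps: 88000, dt: 0.005 s, weighted R-squared: 0.9966
#>   population 1: D = 3.456 um^2/s, fraction = 0.501
#>   population 2: D = 0.5006 um^2/s, fraction = 0.499
```

The true generating values were D = 3.5 and 0.5 µm²·s⁻¹ in equal fractions;
the m = 2 model was chosen because the single-population fit fell below the
R² gate.

```r
## motion classes: Brownian, caged and transported tracks
spm <- sim_spec(list(list(model = "brownian", D = 0.5, fraction = 0.4),
                     list(model = "confined", D = 0.5, cage_radius = 0.39,
                          fraction = 0.4),
                     list(model = "directed", D = 0.01, velocity = 1,
                          fraction = 0.2)),
                n_tracks = 500, n_frames = 200, noise_sd = 0.025, seed = 42)
motion <- analyze_motion(simulate_tracks(spm), class_thresholds("conventional"))
print(motion)
#> MSD motion analysis (profile: conventional )
#>   227 classified tracks (+273 discarded)
#>   fractions: free 0.273 / confined 0.176 / active 0.551
#>   mean confinement radius: 0.358 um
```

Per-track class assignments are > 90% correct among classified tracks, and
the mean confinement radius estimates the 0.39 µm cage. Note that the
reported *fractions* are over classified tracks only and the three classes
discard at different rates (directed tracks have a much tighter α
distribution than Brownian ones), so class fractions are not unbiased
estimates of population composition — the same caveat applies to any
analysis using these discard-then-count rules.

```r
## capping stoichiometry at the resting-cell composition
field <- simulate_capping_field(seed = 42)   # 0.41/0.45/0.14 + free RP
pairing <- pair_holoenzymes(field$cp, field$rp)
unit <- estimate_unit_intensity(field$rp$intensity)
print(capping_fractions(pairing, field$rp, unit))
#> Holoenzyme capping stoichiometry
#>   CP (n=2000): free 0.397 / singly 0.471 / doubly 0.132
#>   RP (n=5780): free 0.757 / singly 0.156 / doubly 0.087
#>   16 paired RP clusters above 2.5 units (counted doubly)

## voltage response: 60 s-period modulated, bleaching trace
trace <- simulate_voltage_trace(seed = 42)
print(voltage_response(trace))
#> voltage-response analysis: rate 0.00664 nFI/s (first_min_to_closest_max branch)
#>   5 maxima, 4 minima detected
```

The recovered capping fractions sit within 0.03 of the generating
composition, and the recovered rate is close to amplitude/half-period
(0.2/30 ≈ 0.0067 nFI·s⁻¹).

File-based workflows (`run_spt()`, `run_capping()`, `run_voltage()`) accept
CSV/TIFF inputs with a YAML-configurable parameter set and write JSON
summaries that echo their configuration and seed.

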